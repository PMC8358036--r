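# Independent numeric oracles and fixture builders used across tests.
# These deliberately avoid the code paths they check.

# brute-force Poisson upper tail P(X >= k; lambda) by direct pmf summation
pois_tail_bruteforce <- function(k, lambda) {
  if (k <= 0) return(1)
  i <- seq(k, max(k + 50, ceiling(k + 20 * sqrt(lambda) + 10 * lambda)))
  sum(exp(i * log(lambda) - lambda - lgamma(i + 1)))
}

# brute-force hypergeometric upper tail by pmf enumeration via lchoose
hyper_tail_bruteforce <- function(N, K, n, k) {
  kk <- seq(max(0, n + K - N), min(n, K))
  pmf <- exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n))
  sum(pmf[kk >= k])
}

hyper_pmf_bruteforce <- function(N, K, n) {
  kk <- seq(max(0, n + K - N), min(n, K))
  exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n))
}

toy_genome <- function(lens = c(chr1 = 1e5)) {
  genome_def(names(lens), lens)
}

# random named/scored/stranded intervals for round-trip and overlap tests
random_intervals <- function(n, genome, max_width = 500, seed = 1) {
  withr::with_seed(seed, {
    chroms <- GenomeInfoDb::seqnames(genome)
    lens <- GenomeInfoDb::seqlengths(genome)
    ch <- sample(chroms, n, replace = TRUE)
    w <- sample.int(max_width, n, replace = TRUE)
    s <- vapply(seq_len(n),
                function(i) sample.int(lens[ch[i]] - w[i], 1L), integer(1))
    GenomicRanges::sort(GenomicRanges::GRanges(
      ch, IRanges::IRanges(s, width = w),
      strand = sample(c("+", "-", "*"), n, replace = TRUE),
      name = sprintf("iv%04d", seq_len(n)),
      score = sample.int(1000, n, replace = TRUE),
      seqinfo = genome), ignore.strand = TRUE)
  })
}

# O(n^2) all-pairs overlap oracle: indices of a overlapping >= min_ov bp of b
bruteforce_overlaps <- function(a, b, min_ov = 1) {
  achr <- as.character(GenomicRanges::seqnames(a))
  bchr <- as.character(GenomicRanges::seqnames(b))
  as <- GenomicRanges::start(a); ae <- GenomicRanges::end(a)
  bs <- GenomicRanges::start(b); be <- GenomicRanges::end(b)
  vapply(seq_along(a), function(i) {
    any(bchr == achr[i] &
          pmin(ae[i], be) - pmax(as[i], bs) + 1 >= min_ov)
  }, logical(1))
}

# 1-bp GRanges at truth lesion positions
lesion_points <- function(lesions, genome) {
  GenomicRanges::GRanges(lesions$chrom,
                         IRanges::IRanges(lesions$pos, width = 1),
                         seqinfo = genome)
}

# quick small simulation config for pipeline-level tests
small_config <- function(seed = 3L, ...) {
  over <- list(...)
  sim <- c(list(genome = list(chrA = 4e6, chrB = 4e6),
                n_lesions = 40, n_tf_sites = 30, n_genes = 400,
                n_upregulated = 40), over)
  validate_config(list(seed = seed, simulation = sim))
}
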