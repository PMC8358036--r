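#' Upper-tail hypergeometric test
#'
#' Core statistic for both enrichment tests: the probability of at least
#' `k` successes in `n` draws without replacement from a population of `N`
#' containing `K` successes. Computed in log space so extreme tails do not
#' underflow; `log10_p` is always finite and reported alongside `p_upper`.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n draws.
#' @param k observed successes.
#' @return an `enrichment_result`: list with `N`, `K`, `n`, `k`, `expected`
#'   (`n*K/N`), `p_upper`, `log10_p`.
#' @export
hyper_test <- function(N, K, n, k) {
  stopifnot(is_count(N), is_count(K), is_count(n), is_count(k))
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(n, K)) stop("k exceeds min(n, K)")
  log_p <- if (k == 0) 0 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  structure(list(N = N, K = K, n = n, k = k, expected = n * K / N,
                 p_upper = exp(log_p), log10_p = log_p / log(10)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Hypergeometric enrichment: k=%d of n=%d (expected %.2f; N=%d, K=%d)\n",
              x$k, x$n, x$expected, x$N, x$K))
  cat(sprintf("  upper-tail p = %.3g (log10 p = %.2f)\n", x$p_upper, x$log10_p))
  invisible(x)
}

#' Single-nearest-gene association for peaks
#'
#' Each peak is associated with the gene whose TSS is closest to the peak
#' midpoint, if within `max_dist` bp; ties go to the lexicographically
#' smaller gene id. Peaks with no TSS within the limit are unassociated.
#'
#' @param peaks `GRanges` of peaks.
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @param max_dist association distance limit in bp (default 1,000,000).
#' @return data.frame: `peak_name`, `gene_id`, `distance` (signed,
#'   TSS minus peak midpoint); one row per associated peak.
#' @export
nearest_gene <- function(peaks, genes, max_dist = 1e6) {
  if (length(peaks) == 0 || nrow(genes) == 0)
    return(data.frame(peak_name = character(0), gene_id = character(0),
                      distance = numeric(0)))
  mid <- GenomicRanges::start(peaks) +
    (GenomicRanges::width(peaks) - 1L) %/% 2L
  pchr <- as.character(GenomicRanges::seqnames(peaks))
  nm <- if (!is.null(peaks$name)) peaks$name else
    sprintf("peak_%d", seq_along(peaks))
  rows <- lapply(seq_along(peaks), function(i) {
    g <- genes[genes$chrom == pchr[i], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    d <- abs(g$tss - mid[i])
    dmin <- min(d)
    if (dmin > max_dist) return(NULL)
    cand <- g[d == dmin, , drop = FALSE]
    gid <- sort(cand$gene_id)[1]  # lexicographic tie-break
    data.frame(peak_name = nm[i], gene_id = gid,
               distance = g$tss[match(gid, g$gene_id)] - mid[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(peak_name = character(0), gene_id = character(0),
                      distance = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# union of sites padded +/- window, clipped to the genome, merged
.padded_target <- function(sites, window, genome) {
  lens <- GenomeInfoDb::seqlengths(genome)[
    as.character(GenomicRanges::seqnames(sites))]
  s <- pmax(GenomicRanges::start(sites) - window, 1)
  e <- pmin(GenomicRanges::end(sites) + window, as.numeric(lens))
  GenomicRanges::reduce(GenomicRanges::GRanges(
    GenomicRanges::seqnames(sites), IRanges::IRanges(s, e), seqinfo = genome),
    ignore.strand = TRUE)
}

#' Peak-to-site proximity enrichment (genome-slot hypergeometric)
#'
#' Tests whether peaks fall within `window` bp (edge distance) of the given
#' sites more often than chance. The genome is modeled as
#' `N = floor(genome_size / mean_peak_length)` slots of which
#' `K = floor(|target| / mean_peak_length)` lie in the target region (the
#' sites padded by `window` and merged); `n` peaks are drawn and `k` of
#' them overlap the target. Validate against [permutation_oracle()].
#'
#' @param peaks `GRanges` of peaks (>= 1).
#' @param sites `GRanges` of TF binding sites (>= 1).
#' @param genome a `Seqinfo`.
#' @param window proximity window in bp (default 10,000).
#' @return an `enrichment_result` with extra fields `mean_peak_length`,
#'   `window`, `target_bp`, and `fraction` (`k/n`).
#' @export
proximity_enrichment <- function(peaks, sites, genome, window = 10000) {
  if (length(peaks) == 0 || length(sites) == 0)
    stop("need at least one peak and one site")
  target <- .padded_target(sites, window, genome)
  lbar <- mean(GenomicRanges::width(peaks))
  if (lbar <= 0) stop("mean peak length is zero")
  N <- floor(genome_size(genome) / lbar)
  K <- floor(sum(as.numeric(GenomicRanges::width(target))) / lbar)
  if (K > N) {
    warning("target larger than genome after padding; clamping K to N")
    K <- N
  }
  n <- length(peaks)
  k <- sum(GenomicRanges::countOverlaps(peaks, target,
                                        ignore.strand = TRUE) > 0)
  res <- hyper_test(N, K, n, k)
  res$mean_peak_length <- lbar
  res$window <- window
  res$target_bp <- sum(as.numeric(GenomicRanges::width(target)))
  res$fraction <- k / n
  res
}

#' Gene-set enrichment of peak-associated genes
#'
#' Hypergeometric overlap between the genes associated with peaks and an
#' upregulated gene set, drawn from a universe of `population_N` genes.
#'
#' @param associated_genes character vector of associated gene ids.
#' @param upregulated_genes character vector of upregulated gene ids.
#' @param population_N size of the gene universe.
#' @return an `enrichment_result`.
#' @export
geneset_enrichment <- function(associated_genes, upregulated_genes,
                               population_N) {
  a <- unique(associated_genes); u <- unique(upregulated_genes)
  if (population_N < length(a) || population_N < length(u))
    stop("population smaller than a gene set")
  hyper_test(population_N, length(u), length(a), length(intersect(a, u)))
}

#' Permutation oracle for the proximity test
#'
#' Re-places every peak uniformly at random on its own chromosome
#' (length-preserving) `n_perm` times and returns the empirical upper-tail
#' probability of the observed target-overlap count, with its Monte-Carlo
#' standard error. Ground-truth check for the slot-based hypergeometric
#' model of [proximity_enrichment()].
#'
#' @inheritParams proximity_enrichment
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `p_empirical`, `se`, `k_obs`, `k_perm` (integer vector
#'   of permuted overlap counts).
#' @export
permutation_oracle <- function(peaks, sites, genome, window = 10000,
                               n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  target <- .padded_target(sites, window, genome)
  k_obs <- sum(GenomicRanges::countOverlaps(peaks, target,
                                            ignore.strand = TRUE) > 0)
  w <- GenomicRanges::width(peaks)
  pchr <- as.character(GenomicRanges::seqnames(peaks))
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  names(lens) <- GenomeInfoDb::seqnames(genome)
  maxstart <- lens[pchr] - w + 1
  ## target as per-chromosome sorted interval matrices for fast lookup
  tchr <- as.character(GenomicRanges::seqnames(target))
  tl <- split(data.frame(s = GenomicRanges::start(target),
                         e = GenomicRanges::end(target)), tchr)
  k_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      st <- floor(stats::runif(length(w)) * maxstart) + 1
      en <- st + w - 1
      hits <- vapply(seq_along(w), function(i) {
        m <- tl[[pchr[i]]]
        !is.null(m) && any(m$s <= en[i] & m$e >= st[i])
      }, logical(1))
      sum(hits)
    }, integer(1))
  })
  p_emp <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
  structure(list(p_empirical = p_emp,
                 se = sqrt(p_emp * (1 - p_emp) / n_perm),
                 k_obs = k_obs, k_perm = k_perm),
            class = "permutation_result")
}
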