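test_that("hypergeometric tail matches exact enumeration", {
  # hand-checkable cases
  expect_equal(hyper_test(50, 10, 5, 5)$p_upper, choose(10, 5) / choose(50, 5),
               tolerance = 1e-12)
  expect_equal(hyper_test(20, 5, 4, 3)$p_upper,
               (choose(5, 3) * choose(15, 1) + choose(5, 4)) / choose(20, 4),
               tolerance = 1e-12)
  expect_equal(hyper_test(100, 30, 10, 0)$p_upper, 1)
  expect_equal(hyper_test(30, 8, 8, 8)$p_upper,
               choose(8, 8) * choose(22, 0) / choose(30, 8), tolerance = 1e-12)

  # random parameter sweep against brute-force pmf summation (N <= 1e4)
  withr::with_seed(3, {
    for (i in 1:40) {
      N <- sample(20:10000, 1)
      K <- sample.int(N, 1)
      n <- sample.int(N, 1)
      k <- sample(max(0, n + K - N):min(n, K), 1)
      got <- hyper_test(N, K, n, k)
      expect_lt(abs(got$p_upper - hyper_tail_bruteforce(N, K, n, k)), 1e-12)
      expect_equal(got$expected, n * K / N)
    }
  })

  # pmf sums to 1 over the support
  for (ps in list(c(100, 40, 25), c(9999, 1234, 567), c(50, 50, 10)))
    expect_lt(abs(sum(hyper_pmf_bruteforce(ps[1], ps[2], ps[3])) - 1), 1e-12)

  # p_upper is non-increasing in k
  ps <- vapply(0:20, function(k) hyper_test(200, 50, 20, k)$p_upper, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))

  # extreme tails stay finite in log space; log10 p reported alongside
  deep <- hyper_test(10000, 500, 400, 150)
  expect_gt(deep$p_upper, 0)
  expect_true(is.finite(deep$log10_p))
  expect_lt(deep$log10_p, -90)
  expect_lt(abs(deep$log10_p - log10(hyper_tail_bruteforce(10000, 500, 400, 150))),
            1e-6)
  # beyond double-precision range, p collapses but log10 p stays informative
  deepest <- hyper_test(10000, 500, 400, 400)
  expect_true(is.finite(deepest$log10_p))
  expect_lt(deepest$log10_p, deep$log10_p)

  expect_error(hyper_test(10, 5, 4, 5), "exceeds")
  expect_error(hyper_test(10, 12, 4, 2), "exceed N")
})

test_that("single-nearest-gene association uses midpoint, limit, and tie rule", {
  g <- toy_genome(c(chr1 = 1e7))
  genes <- data.frame(gene_id = c("geneB", "geneA", "geneC"),
                      chrom = "chr1", tss = c(5000, 7000, 3000000),
                      strand = "+")
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4901, 5100),
                               name = "p1", seqinfo = g)  # midpoint 5000
  a <- nearest_gene(pk, genes)
  expect_equal(a$gene_id, "geneB")
  expect_equal(a$distance, 0)

  # equidistant TSSs -> lexicographically smaller id
  pk2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5901, 6100),
                                name = "p2", seqinfo = g)  # midpoint 6000
  expect_equal(nearest_gene(pk2, genes)$gene_id, "geneA")

  # exactly at the 1000 kb limit -> still associated; one bp beyond -> not
  at_limit <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(3999901, 4000100), name = "p4", seqinfo = g)
  expect_equal(nearest_gene(at_limit, genes)$gene_id, "geneC")  # d = 1e6
  beyond <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(4000902, 4001101), name = "p5", seqinfo = g)
  expect_equal(nrow(nearest_gene(beyond, genes)), 0)       # d = 1,000,001
})

test_that("proximity enrichment detects planted TF-site coupling", {
  g <- toy_genome(c(chrA = 2e7))
  p <- sim_params(n_lesions = 200, f_prox = 0.5, w_prox = 10000, mu = 80,
                  background_rate = 0, replicate_jaccard = 1,
                  n_tf_sites = 200, n_genes = 100, n_upregulated = 10,
                  seed = 9)
  tr <- make_truth(p, g)
  tg <- simulate_endseq(tr, 1)
  pk <- call_peaks(tg, g)
  res <- proximity_enrichment(pk, tr$tf_sites, g, window = 10000)
  expect_gte(res$k, 0.4 * res$n)
  expect_lt(res$p_upper, 1e-6)
  expect_equal(res$fraction, res$k / res$n)
  expect_equal(res$N, floor(genome_size(g) / res$mean_peak_length))
})

test_that("permutation oracle is deterministic and saturates correctly", {
  g <- toy_genome(c(chr1 = 1e6))
  pk <- random_intervals(30, g, max_width = 200, seed = 5)
  sites <- random_intervals(10, g, max_width = 400, seed = 6)
  r1 <- permutation_oracle(pk, sites, g, window = 10000, n_perm = 100, seed = 7)
  r2 <- permutation_oracle(pk, sites, g, window = 10000, n_perm = 100, seed = 7)
  expect_identical(r1$k_perm, r2$k_perm)
  expect_error(permutation_oracle(pk, sites, g, n_perm = 10), "n_perm")

  # sites covering the whole genome: every placement overlaps, p = 1
  all_sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6),
                                      seqinfo = g)
  rs <- permutation_oracle(pk, all_sites, g, window = 0, n_perm = 100, seed = 1)
  expect_equal(rs$p_empirical, 1)
  expect_true(all(rs$k_perm == length(pk)))
})

test_that("gene-set enrichment counts overlaps in a bounded universe", {
  up <- sprintf("g%03d", 1:30)
  assoc <- c(sprintf("g%03d", 11:20), sprintf("x%03d", 1:10))
  res <- geneset_enrichment(assoc, up, 500)
  expect_equal(res$k, 10); expect_equal(res$n, 20); expect_equal(res$K, 30)
  expect_lt(abs(res$p_upper - hyper_tail_bruteforce(500, 30, 20, 10)), 1e-12)
  # disjoint sets
  expect_equal(geneset_enrichment(c("a", "b"), c("c"), 100)$p_upper, 1)
  expect_error(geneset_enrichment(as.character(1:50), up, 40), "population")
})
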