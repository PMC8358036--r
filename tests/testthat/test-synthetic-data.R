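test_that("ground truth is deterministic and honors proximity by construction", {
  g <- toy_genome(c(chrA = 4e6, chrB = 4e6))
  p <- sim_params(n_lesions = 40, n_tf_sites = 30, n_genes = 200,
                  n_upregulated = 20, seed = 11)
  t1 <- make_truth(p, g)
  t2 <- make_truth(p, g)
  expect_identical(t1$lesions, t2$lesions)
  expect_identical(t1$upregulated, t2$upregulated)
  expect_identical(GenomicRanges::start(t1$tf_sites),
                   GenomicRanges::start(t2$tf_sites))

  # exactly floor(f_prox * n) lesions within w_prox of a site (edge distance)
  lp <- lesion_points(t1$lesions, g)
  near <- GenomicRanges::countOverlaps(
    lp, t1$tf_sites + p$w_prox, ignore.strand = TRUE) > 0
  expect_equal(sum(near), floor(p$f_prox * p$n_lesions))

  # f_prox = 1: every lesion proximal
  pa <- sim_params(n_lesions = 50, f_prox = 1, n_tf_sites = 60,
                   n_genes = 100, n_upregulated = 10, seed = 2)
  ta <- make_truth(pa, g)
  lpa <- lesion_points(ta$lesions, g)
  expect_true(all(GenomicRanges::countOverlaps(
    lpa, ta$tf_sites + pa$w_prox, ignore.strand = TRUE) > 0))

  # n_lesions = 0: empty lesions, sites still there
  p0 <- sim_params(n_lesions = 0, n_genes = 100, n_upregulated = 10, seed = 5)
  t0 <- make_truth(p0, g)
  expect_equal(nrow(t0$lesions), 0)
  expect_gt(length(t0$tf_sites), 0)

  # minimum spacing between lesions
  by_chr <- split(t1$lesions$pos, t1$lesions$chrom)
  for (v in by_chr)
    if (length(v) > 1) expect_true(min(diff(sort(v))) >= p$min_spacing)

  # infeasible placement errors out
  tiny <- toy_genome(c(chr1 = 5e4))
  expect_error(make_truth(sim_params(n_lesions = 50, n_tf_sites = 5,
                                     n_genes = 10, n_upregulated = 1,
                                     seed = 1), tiny),
               "infeasible")
})

test_that("simulated tags follow the strand-resolved end-capture model", {
  g <- toy_genome(c(chr1 = 1e6))
  # one DSB, no background: both strands ~ Poisson(mu), tags near the break
  p <- sim_params(n_lesions = 1, frac_dsb = 1, f_prox = 0, mu = 100,
                  background_rate = 0, replicate_jaccard = 1,
                  n_tf_sites = 5, n_genes = 50, n_upregulated = 5, seed = 21)
  tr <- make_truth(p, g)
  tg <- simulate_endseq(tr, 1)
  std <- as.character(GenomicRanges::strand(tg))
  np <- sum(std == "+"); nm <- sum(std == "-")
  expect_lt(abs(np - 100), 4 * sqrt(100))
  expect_lt(abs(nm - 100), 4 * sqrt(100))
  x <- tr$lesions$pos[1]
  expect_true(all(abs(GenomicRanges::start(tg) - x) < 50 * p$resection_scale))
  # orientation: plus tags right of the break, minus tags left
  expect_true(all(GenomicRanges::start(tg)[std == "+"] >= x))
  expect_true(all(GenomicRanges::start(tg)[std == "-"] <= x))

  # one SSB on plus: zero minus-strand tags
  ps <- sim_params(n_lesions = 1, frac_dsb = 0, f_prox = 0, mu = 100,
                   background_rate = 0, replicate_jaccard = 1,
                   n_tf_sites = 5, n_genes = 50, n_upregulated = 5, seed = 8)
  ts <- make_truth(ps, g)
  tgs <- simulate_endseq(ts, 1)
  want <- ts$lesions$ssb_strand[1]
  expect_true(all(as.character(GenomicRanges::strand(tgs)) == want))

  # background only: total ~ Poisson(2 * rate * G)
  pb <- sim_params(n_lesions = 0, background_rate = 1e-3,
                   n_tf_sites = 5, n_genes = 50, n_upregulated = 5, seed = 13)
  gb <- toy_genome(c(chr1 = 1e7))
  tb <- make_truth(pb, gb)
  tgb <- simulate_endseq(tb, 1)
  mu_tot <- 2 * 1e-3 * 1e7
  expect_lt(abs(length(tgb) - mu_tot), 5 * sqrt(mu_tot))

  # determinism per replicate, difference across replicates
  again <- simulate_endseq(tr, 1)
  expect_identical(GenomicRanges::start(tg), GenomicRanges::start(again))
  other <- simulate_endseq(tr, 2)
  expect_false(identical(GenomicRanges::start(tg),
                         GenomicRanges::start(other)))
})

test_that("replicate inclusion matches the tag-level draw and jaccard rate", {
  g <- toy_genome(c(chrA = 2e7))
  p <- sim_params(n_lesions = 150, replicate_jaccard = 0.85,
                  background_rate = 0, n_tf_sites = 60, n_genes = 100,
                  n_upregulated = 10, seed = 31)
  tr <- make_truth(p, g)
  inc <- lesion_inclusion(tr, 1)
  tg <- simulate_endseq(tr, 1)
  expect_identical(S4Vectors::metadata(tg)$included, inc)
  # included lesions produce nearby tags; excluded ones do not (bg = 0)
  lp <- lesion_points(tr$lesions, g)
  n_near <- GenomicRanges::countOverlaps(lp + 5000, tg, ignore.strand = TRUE)
  expect_true(all(n_near[inc] > 0))
  expect_true(all(n_near[!inc] == 0))
  expect_lt(abs(mean(inc) - 0.85), 4 * sqrt(0.85 * 0.15 / 150))
})

test_that("DSB-only simulations are strand-symmetric on average", {
  g <- toy_genome(c(chrA = 2e7))
  p <- sim_params(n_lesions = 100, frac_dsb = 1, mu = 80,
                  background_rate = 0, replicate_jaccard = 1,
                  n_tf_sites = 60, n_genes = 100, n_upregulated = 10,
                  seed = 17)
  tr <- make_truth(p, g)
  tg <- simulate_endseq(tr, 1)
  lp <- lesion_points(tr$lesions, g) + 2000
  std <- as.character(GenomicRanges::strand(tg))
  plus <- GenomicRanges::countOverlaps(lp, tg[std == "+"], ignore.strand = TRUE)
  minus <- GenomicRanges::countOverlaps(lp, tg[std == "-"], ignore.strand = TRUE)
  lr <- strand_log_ratio(plus, minus)
  # per-lesion log-ratio sd ~ sqrt(2/mu)/ln2; mean of 100 lesions near zero
  expect_lt(abs(mean(lr)), 4 * sqrt(2 / p$mu) / log(2) / sqrt(100))
  expect_true(all(abs(lr) <= 1))  # all classified symmetric at mu = 80
})

test_that("gene universe enrichment biases the upregulated set toward lesions", {
  g <- toy_genome(c(chrA = 4e6, chrB = 4e6))
  base <- sim_params(n_lesions = 20, n_tf_sites = 30, n_genes = 200,
                     n_upregulated = 20, upreg_enrichment = 1, seed = 41)
  tr <- make_truth(base, g)
  expect_error(sim_params(n_genes = 10, n_upregulated = 11), "exceeds")

  # empirical upregulated-hit rate of lesion-nearest genes over 200 draws
  hit_rate <- function(factor) {
    p <- sim_params(n_lesions = 20, n_tf_sites = 30, n_genes = 200,
                    n_upregulated = 20, upreg_enrichment = factor, seed = 41)
    lesg <- GenomicRanges::GRanges(tr$lesions$chrom,
                                   IRanges::IRanges(tr$lesions$pos, width = 1))
    mean(vapply(1:200, function(s) {
      gu <- make_gene_universe(p, g, tr$lesions, seed = s)
      assoc <- nearest_gene(lesg, gu$genes)
      mean(assoc$gene_id %in% gu$upregulated)
    }, numeric(1)))
  }
  expect_gt(hit_rate(50), 0.2)       # strongly above the 10% baseline
  expect_lt(abs(hit_rate(1) - 0.1), 0.05)  # uniform draw stays near baseline
})

test_that("truth files round-trip and re-validate against emitted tags", {
  g <- toy_genome(c(chrA = 4e6))
  p <- sim_params(n_lesions = 15, background_rate = 0, replicate_jaccard = 1,
                  n_tf_sites = 20, n_genes = 50, n_upregulated = 5, seed = 6)
  tr <- make_truth(p, g)
  d <- withr::local_tempdir()
  write_truth(tr, d)
  les <- utils::read.table(file.path(d, "lesions.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  expect_equal(les$pos, tr$lesions$pos)
  genes <- read_tss_table(file.path(d, "genes.tsv"), g)
  expect_equal(genes$gene_id, tr$genes$gene_id)
  expect_equal(read_gene_list(file.path(d, "upregulated.txt")),
               sort(tr$upregulated))
  sites <- read_bed(file.path(d, "tf_sites.bed"), g)
  expect_equal(GenomicRanges::start(sites), GenomicRanges::start(tr$tf_sites))
  # every lesion in the truth file is supported by nearby emitted tags
  tg <- simulate_endseq(tr, 1)
  lp <- GenomicRanges::GRanges(les$chrom, IRanges::IRanges(les$pos, width = 1),
                               seqinfo = g)
  expect_true(all(GenomicRanges::countOverlaps(lp + 5000, tg,
                                               ignore.strand = TRUE) > 0))
})
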