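test_that("chrom.sizes parsing preserves order and validates input", {
  tf <- withr::local_tempfile()
  writeLines(c("chr1\t1000", "chr2\t500"), tf)
  g <- read_chrom_sizes(tf)
  expect_equal(GenomeInfoDb::seqnames(g), c("chr1", "chr2"))
  expect_equal(genome_size(g), 1500)

  writeLines(character(0), tf)
  expect_error(read_chrom_sizes(tf), "no chromosomes")

  writeLines(c("chr1\t1000", "chr1\t900"), tf)
  expect_error(read_chrom_sizes(tf), "duplicate")

  writeLines(c("chr1\t1000", "chr2\t-5"), tf)
  expect_error(read_chrom_sizes(tf), "non-positive")

  writeLines(c("chr1\t1000", "chr2 five-hundred"), tf)
  expect_error(read_chrom_sizes(tf), "line 2")
})

test_that("BED reading validates coordinates, strand, and chromosomes", {
  g <- toy_genome(c(chr1 = 1000))
  tf <- withr::local_tempfile(fileext = ".bed")

  writeLines("chr1\t10\t20", tf)
  gr <- read_bed(tf, g)
  expect_length(gr, 1)
  expect_equal(GenomicRanges::width(gr), 10)  # half-open BED length

  writeLines("chr1\t20\t20", tf)
  expect_error(read_bed(tf, g), "start >= end|parse error")
  writeLines("chr1\t20\t10", tf)
  expect_error(read_bed(tf, g), "start >= end|parse error")

  writeLines("chr1\t10\t20\tx\t0\t-", tf)
  expect_equal(as.character(GenomicRanges::strand(read_bed(tf, g))), "-")

  writeLines(c("chr1\t10\t20", "chrUn\t5\t9"), tf)
  expect_warning(gr <- read_bed(tf, g), "unknown")
  expect_length(gr, 1)
  expect_error(read_bed(tf, g, on_unknown = "error"), "unknown")

  writeLines("chr1\t10\t2000", tf)
  expect_error(read_bed(tf, g), "out-of-bounds")
  gr <- read_bed(tf, g, clip = TRUE)
  expect_equal(GenomicRanges::end(gr), 1000)
})

test_that("BED round-trip is the identity on random interval sets", {
  g <- toy_genome(c(chr1 = 1e5, chr2 = 5e4))
  for (seed in c(1, 42)) {
    iv <- random_intervals(100, g, seed = seed)
    tf <- withr::local_tempfile(fileext = ".bed")
    write_bed(iv, tf)
    back <- read_bed(tf, g)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(iv))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(iv))
    expect_equal(as.character(GenomicRanges::seqnames(back)),
                 as.character(GenomicRanges::seqnames(iv)))
    expect_equal(as.character(GenomicRanges::strand(back)),
                 as.character(GenomicRanges::strand(iv)))
    expect_equal(back$name, iv$name)
    expect_equal(back$score, iv$score)
  }
})

test_that("downstream containers arrive sorted regardless of input order", {
  g <- toy_genome(c(chr1 = 1e5, chr2 = 5e4))
  iv <- random_intervals(50, g, seed = 9)
  shuf <- withr::with_seed(4, iv[sample.int(length(iv))])
  tf <- withr::local_tempfile(fileext = ".bed")
  write_bed(shuf, tf)
  back <- read_bed(tf, g)
  expect_equal(as.character(GenomicRanges::seqnames(back)),
               as.character(GenomicRanges::seqnames(iv)))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(iv))
})

test_that("tag loading reduces read intervals to 5' ends by strand", {
  g <- toy_genome(c(chr1 = 1000))
  tf <- withr::local_tempfile(fileext = ".bed")
  # plus read [10,20) -> 5' end at BED 10 (1-based 11)
  # minus read [30,50) -> 5' end at BED 49 (1-based 50)
  writeLines(c("chr1\t10\t20\tr1\t0\t+", "chr1\t30\t50\tr2\t0\t-"), tf)
  tg <- read_tags(tf, g)
  expect_equal(GenomicRanges::start(tg), c(11L, 50L))
  expect_equal(GenomicRanges::width(tg), c(1L, 1L))
  expect_equal(as.character(GenomicRanges::strand(tg)), c("+", "-"))

  writeLines("chr1\t10\t20", tf)  # unstranded
  expect_error(read_tags(tf, g), "stranded")

  # tags round-trip through BED6
  out <- withr::local_tempfile(fileext = ".bed")
  write_tags(tg, out)
  back <- read_tags(out, g)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(tg))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(tg)))
})

test_that("bedGraph output merges equal-value runs and omits zeros", {
  g <- toy_genome(c(chr1 = 75))
  # bins of 25 bp with values [1,1,2]
  tg <- make_tags(rep("chr1", 4), c(5, 30, 55, 60), rep("+", 4), g)
  tr <- make_track(tg, g, bin_size = 25)
  expect_equal(tr$values$chr1, c(1, 1, 2))
  gr <- track_to_granges(tr)
  expect_length(gr, 2)
  expect_equal(GenomicRanges::start(gr), c(1L, 51L))
  expect_equal(GenomicRanges::end(gr), c(50L, 75L))
  expect_equal(gr$score, c(1, 2))

  # all-zero track -> empty bedGraph by default
  empty <- make_track(make_tags(character(0), integer(0), character(0), g), g,
                      bin_size = 25)
  expect_length(track_to_granges(empty), 0)
  expect_length(track_to_granges(empty, keep_zeros = TRUE), 1)

  # round-trip through the file
  tf <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, tf)
  back <- read_bedgraph(tf, g, bin_size = 25)
  expect_equal(back$values$chr1, tr$values$chr1)
})
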