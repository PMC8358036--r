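#' Build a binned, optionally smoothed and RPKM-normalized signal track
#'
#' Raw bin values are tag counts per bin; RPKM values are
#' `count * 1e9 / (total_tags * bin_size)` with `total_tags` the full
#' library size (both strands, before any strand filtering). Smoothing is a
#' centered moving average over `smooth_length / bin_size` bins; edge bins
#' average over the available (truncated) window.
#'
#' @param tags width-1 `GRanges` of stranded tags.
#' @param genome a `Seqinfo`.
#' @param bin_size bin width in bp (default 25).
#' @param smooth_length smoothing window in bp (0 = none; default 0; the
#'   conventional track setting is 75 with 25-bp bins).
#' @param normalization `"raw"` counts or `"rpkm"`.
#' @param strand_filter `"both"`, `"+"`, or `"-"`.
#' @return a `coverage_track`: list with `bin_size`, `values` (named list of
#'   per-chromosome numeric vectors), `normalization`, `smooth_length`,
#'   `total_tags`, `genome`.
#' @export
make_track <- function(tags, genome, bin_size = 25, smooth_length = 0,
                       normalization = c("raw", "rpkm"),
                       strand_filter = c("both", "+", "-")) {
  normalization <- match.arg(normalization)
  strand_filter <- match.arg(strand_filter)
  if (bin_size <= 0) stop("bin_size must be positive")
  total <- length(tags)
  use <- tags
  if (strand_filter != "both")
    use <- tags[as.character(GenomicRanges::strand(tags)) == strand_filter]
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  names(lens) <- chroms
  pos_by <- split(GenomicRanges::start(use),
                  factor(as.character(GenomicRanges::seqnames(use)),
                         levels = chroms))
  values <- lapply(stats::setNames(as.list(chroms), chroms), function(ch) {
    nb <- ceiling(lens[ch] / bin_size)
    v <- tabulate((pos_by[[ch]] - 1) %/% bin_size + 1, nbins = nb)
    if (normalization == "rpkm") {
      if (total == 0) v <- as.numeric(v)
      else v <- v * 1e9 / (total * bin_size)
    }
    if (smooth_length > 0) v <- .smooth_centered(v, smooth_length, bin_size)
    as.numeric(v)
  })
  structure(list(bin_size = bin_size, values = values,
                 normalization = normalization, smooth_length = smooth_length,
                 total_tags = total, genome = genome),
            class = "coverage_track")
}

# centered moving average over k = smooth_length/bin_size bins (forced odd),
# truncated at chromosome edges
.smooth_centered <- function(x, smooth_length, bin_size) {
  k <- max(1L, round(smooth_length / bin_size))
  if (k %% 2 == 0) k <- k + 1L
  if (k == 1L) return(as.numeric(x))
  n <- length(x)
  h <- (k - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
  cs <- c(0, cumsum(as.numeric(x)))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Downsample a tag library to a target depth
#'
#' Uniform sampling without replacement over all tags jointly (both strands
#' together, as whole libraries are depth-matched). Deterministic given
#' `seed`.
#'
#' @param tags width-1 `GRanges` of tags.
#' @param target_count number of tags to keep.
#' @param seed integer seed.
#' @return sorted `GRanges` with `target_count` tags.
#' @export
downsample_tags <- function(tags, target_count, seed = 1L) {
  if (target_count > length(tags))
    stop("target_count exceeds total tag count")
  if (target_count == length(tags)) return(tags)
  idx <- with_seed(seed, sample.int(length(tags), target_count))
  GenomicRanges::sort(tags[sort(idx)], ignore.strand = TRUE)
}

#' Convert a coverage track to a run-length merged GRanges
#'
#' Runs of equal-valued adjacent bins are merged into single intervals
#' (bedGraph convention); zero-valued runs are omitted by default.
#'
#' @param track a `coverage_track`.
#' @param keep_zeros keep zero-valued runs.
#' @return `GRanges` with a `score` column.
#' @export
track_to_granges <- function(track, keep_zeros = FALSE) {
  genome <- track$genome
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  names(lens) <- GenomeInfoDb::seqnames(genome)
  parts <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1
    keep <- if (keep_zeros) rep(TRUE, length(r$values)) else r$values != 0
    if (!any(keep)) return(NULL)
    s <- (starts_bin[keep] - 1) * track$bin_size + 1
    e <- pmin(ends_bin[keep] * track$bin_size, lens[ch])
    GenomicRanges::GRanges(ch, IRanges::IRanges(s, e),
                           score = r$values[keep], seqinfo = genome)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0)
    return(GenomicRanges::GRanges(seqinfo = genome, score = numeric(0)))
  GenomicRanges::sort(do.call(c, parts), ignore.strand = TRUE)
}

#' Write a coverage track as bedGraph
#' @param track a `coverage_track`.
#' @param path output path.
#' @param keep_zeros keep zero-valued runs.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, keep_zeros = FALSE) {
  rtracklayer::export(track_to_granges(track, keep_zeros), path,
                      format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph back into a coverage track
#'
#' Intervals are expanded onto a fixed bin grid; intervals must align to
#' bin boundaries (as written by [write_bedgraph()]).
#'
#' @param path bedGraph path.
#' @param genome a `Seqinfo`.
#' @param bin_size bin width the file was written with.
#' @return a `coverage_track` (normalization/smoothing provenance unknown,
#'   recorded as `"raw"`, 0).
#' @export
read_bedgraph <- function(path, genome, bin_size) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  names(lens) <- chroms
  values <- lapply(stats::setNames(as.list(chroms), chroms), function(ch) {
    nb <- ceiling(lens[ch] / bin_size)
    v <- numeric(nb)
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    if (length(sub)) {
      b0 <- (GenomicRanges::start(sub) - 1) %/% bin_size + 1
      b1 <- (GenomicRanges::end(sub) - 1) %/% bin_size + 1
      for (i in seq_along(sub)) v[b0[i]:b1[i]] <- sub$score[i]
    }
    v
  })
  structure(list(bin_size = bin_size, values = values, normalization = "raw",
                 smooth_length = 0, total_tags = NA_integer_, genome = genome),
            class = "coverage_track")
}
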