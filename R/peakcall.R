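#' Peak caller parameters
#'
#' The caller mirrors the semantics of MACS run with a genome-wide uniform
#' background and no fragment model: no local lambda (`lambda_mode =
#' "global"`), tags used as-is, duplicates kept. An optional control track
#' supplies a per-window lambda floored at the global rate.
#'
#' @param window sliding-window width in bp.
#' @param step window step in bp; must divide `window`.
#' @param p_threshold raw upper-tail Poisson p-value cutoff.
#' @param min_gap merge significant regions separated by at most this many bp.
#' @param min_length drop merged regions shorter than this.
#' @param lambda_mode `"global"` or `"control"`.
#' @param control optional raw `coverage_track` with `bin_size == step`,
#'   required for `lambda_mode = "control"`.
#' @return a validated `caller_params` list.
#' @export
caller_params <- function(window = 200, step = 50, p_threshold = 1e-5,
                          min_gap = 100, min_length = 50,
                          lambda_mode = c("global", "control"),
                          control = NULL) {
  lambda_mode <- match.arg(lambda_mode)
  if (step > window) stop("step must be <= window")
  if (window %% step != 0) stop("window must be a multiple of step")
  if (!(p_threshold > 0 && p_threshold < 1)) stop("p_threshold must be in (0,1)")
  if (min_gap < 0 || min_length < 0) stop("min_gap/min_length must be >= 0")
  if (lambda_mode == "control") {
    if (is.null(control)) stop("control track required for lambda_mode='control'")
    if (control$bin_size != step) stop("control bin_size must equal step")
  }
  structure(list(window = window, step = step, p_threshold = p_threshold,
                 min_gap = min_gap, min_length = min_length,
                 lambda_mode = lambda_mode, control = control),
            class = "caller_params")
}

#' Scan sliding windows and compute Poisson upper-tail p-values
#'
#' Both strands are pooled and all tags kept. The global background is
#' `lambda = total_tags * window / genome_size`. Each window of `window` bp,
#' stepped by `step`, is tested with `P(X >= k; lambda)` (log-space, no
#' underflow).
#'
#' @param tags width-1 `GRanges` of tags.
#' @param genome a `Seqinfo`.
#' @param params a [caller_params()] object.
#' @return data.frame: `chrom`, `start`, `end` (1-based closed), `count`,
#'   `lambda`, `log_p` (natural log of the upper-tail p).
#' @export
window_scan <- function(tags, genome, params = caller_params()) {
  if (length(tags) == 0) stop("empty tag set")
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  names(lens) <- chroms
  if (params$window > min(lens)) stop("window exceeds shortest chromosome")
  lambda_g <- length(tags) * params$window / genome_size(genome)
  w_bins <- params$window %/% params$step
  pos_by <- split(GenomicRanges::start(tags),
                  factor(as.character(GenomicRanges::seqnames(tags)),
                         levels = chroms))
  out <- lapply(chroms, function(ch) {
    nb <- floor(lens[ch] / params$step)
    if (nb < w_bins) return(NULL)
    b <- tabulate((pos_by[[ch]] - 1) %/% params$step + 1, nbins = nb)
    cs <- c(0, cumsum(as.numeric(b)))
    nw <- nb - w_bins + 1
    i <- seq_len(nw)
    counts <- cs[i + w_bins] - cs[i]
    lam <- rep(lambda_g, nw)
    if (params$lambda_mode == "control") {
      cb <- params$control$values[[ch]]
      ccs <- c(0, cumsum(as.numeric(cb[seq_len(nb)])))
      ctot <- sum(vapply(params$control$values, sum, numeric(1)))
      scale <- if (ctot > 0) length(tags) / ctot else 0
      lam_c <- (ccs[i + w_bins] - ccs[i]) * scale
      lam <- pmax(lam_c, lambda_g)
    }
    data.frame(chrom = ch,
               start = (i - 1) * params$step + 1,
               end = (i - 1) * params$step + params$window,
               count = counts, lambda = lam,
               log_p = stats::ppois(counts - 1, lam, lower.tail = FALSE,
                                    log.p = TRUE))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Call peaks from stranded tags with a global Poisson background
#'
#' Significant windows (raw p below `p_threshold`) are unioned, regions
#' separated by at most `min_gap` bp merged, and merged regions shorter than
#' `min_length` dropped. Each peak carries its summit (center of the
#' max-count step bin, leftmost on ties), per-strand tag intensities over
#' the final interval, and `score = -log10` of its best window p-value.
#'
#' @inheritParams window_scan
#' @return sorted `GRanges` with mcols `name`, `score`, `summit`,
#'   `plus_intensity`, `minus_intensity`.
#' @export
call_peaks <- function(tags, genome, params = caller_params()) {
  scan <- window_scan(tags, genome, params)
  sig <- scan[scan$log_p < log(params$p_threshold), , drop = FALSE]
  if (nrow(sig) == 0)
    return(GenomicRanges::GRanges(seqinfo = genome, name = character(0),
                                  score = numeric(0), summit = integer(0),
                                  plus_intensity = integer(0),
                                  minus_intensity = integer(0)))
  win <- GenomicRanges::GRanges(sig$chrom, IRanges::IRanges(sig$start, sig$end),
                                seqinfo = genome)
  merged <- GenomicRanges::reduce(win, min.gapwidth = params$min_gap + 1)
  merged <- merged[GenomicRanges::width(merged) >= params$min_length]
  if (length(merged) == 0)
    return(GenomicRanges::GRanges(seqinfo = genome, name = character(0),
                                  score = numeric(0), summit = integer(0),
                                  plus_intensity = integer(0),
                                  minus_intensity = integer(0)))
  merged <- GenomicRanges::sort(merged, ignore.strand = TRUE)

  ## best (lowest) window log-p per peak
  hit <- GenomicRanges::findOverlaps(merged, win)
  best <- tapply(sig$log_p[S4Vectors::subjectHits(hit)],
                 S4Vectors::queryHits(hit), min)
  score <- -best[as.character(seq_along(merged))] / log(10)

  ## summit: center of the max-count step bin within the peak
  summit <- integer(length(merged))
  pchr <- as.character(GenomicRanges::seqnames(merged))
  for (i in seq_along(merged)) {
    s <- GenomicRanges::start(merged)[i]; e <- GenomicRanges::end(merged)[i]
    sel <- GenomicRanges::start(tags) >= s & GenomicRanges::end(tags) <= e &
      as.character(GenomicRanges::seqnames(tags)) == pchr[i]
    p <- GenomicRanges::start(tags)[sel]
    nb <- (e - s + 1) %/% params$step + 1
    bc <- tabulate((p - s) %/% params$step + 1, nbins = nb)
    j <- which.max(bc)  # leftmost on ties
    bs <- s + (j - 1) * params$step
    be <- min(e, bs + params$step - 1)
    summit[i] <- bs + (be - bs) %/% 2
  }

  plus <- GenomicRanges::countOverlaps(
    merged, tags[as.character(GenomicRanges::strand(tags)) == "+"],
    ignore.strand = TRUE)
  minus <- GenomicRanges::countOverlaps(
    merged, tags[as.character(GenomicRanges::strand(tags)) == "-"],
    ignore.strand = TRUE)

  S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
    name = sprintf("peak_%d", seq_along(merged)),
    score = as.numeric(score), summit = summit,
    plus_intensity = plus, minus_intensity = minus)
  merged
}

#' Remove peaks overlapping blacklisted regions
#'
#' A single bp of overlap with any blacklist interval removes the peak;
#' order is preserved.
#'
#' @param peaks `GRanges` of peaks.
#' @param blacklist `GRanges` of blacklisted regions.
#' @return filtered `GRanges`.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (length(blacklist) == 0) return(peaks)
  peaks[GenomicRanges::countOverlaps(peaks, blacklist,
                                     ignore.strand = TRUE) == 0]
}

#' Write peaks as a narrowPeak-like TSV
#' @param peaks peak `GRanges` from [call_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,  # BED half-open
                   end = GenomicRanges::end(peaks),
                   name = peaks$name,
                   score = as.integer(round(pmin(peaks$score * 10, 1000))),
                   strand = ".",
                   plus_intensity = peaks$plus_intensity,
                   minus_intensity = peaks$minus_intensity,
                   neg_log10_p = peaks$score,
                   summit_offset = peaks$summit - GenomicRanges::start(peaks))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
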