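#' Per-peak strand signal log-ratio
#'
#' `log2((plus + c) / (minus + c))` with pseudocount `c` keeping the ratio
#' finite at zero counts. On this scale the symmetric (double-strand) band
#' `[-1, 1]` corresponds to at most a two-fold strand imbalance.
#'
#' @param plus,minus per-strand tag counts (non-negative, vectorized).
#' @param pseudocount pseudocount added per strand (> 0, default 1).
#' @return numeric log2 ratio(s).
#' @export
strand_log_ratio <- function(plus, minus, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(plus < 0) || any(minus < 0)) stop("negative intensity")
  log2((plus + pseudocount) / (minus + pseudocount))
}

#' Classify a strand log-ratio as symmetric or asymmetric
#'
#' Symmetric (double-strand break) iff the log-ratio lies in
#' `[-band, band]` (closed interval); otherwise asymmetric (single-strand)
#' with dominant strand `+` above the band and `-` below it.
#'
#' @param log_ratio numeric log2 strand ratio(s); must be finite.
#' @param band half-width of the symmetric band (default 1).
#' @return data.frame with `class` (`"symmetric"`/`"asymmetric"`) and
#'   `dominant_strand` (`"."`, `"+"`, `"-"`).
#' @export
classify_ratio <- function(log_ratio, band = 1) {
  if (any(is.na(log_ratio)) || any(!is.finite(log_ratio)))
    stop("log_ratio must be finite")
  sym <- abs(log_ratio) <= band
  data.frame(class = ifelse(sym, "symmetric", "asymmetric"),
             dominant_strand = ifelse(sym, ".",
                                      ifelse(log_ratio > band, "+", "-")),
             stringsAsFactors = FALSE)
}

#' Classify peaks into lesion calls
#'
#' Adds `log_ratio`, `class`, and `dominant_strand` columns computed from
#' the peaks' raw per-strand tag intensities.
#'
#' @param peaks peak `GRanges` with `plus_intensity`/`minus_intensity`
#'   mcols (from [call_peaks()], or recomputed via [peak_intensities()]).
#' @param pseudocount pseudocount per strand.
#' @param band symmetric band half-width.
#' @return the peaks with classification mcols added.
#' @export
classify_lesions <- function(peaks, pseudocount = 1, band = 1) {
  lr <- strand_log_ratio(peaks$plus_intensity, peaks$minus_intensity,
                         pseudocount)
  cl <- classify_ratio(lr, band)
  S4Vectors::mcols(peaks)$log_ratio <- lr
  S4Vectors::mcols(peaks)$class <- cl$class
  S4Vectors::mcols(peaks)$dominant_strand <- cl$dominant_strand
  peaks
}

#' Recompute per-strand tag intensities over given intervals
#'
#' Useful for scoring consensus intervals against an individual clone's
#' tag library.
#'
#' @param peaks `GRanges` of intervals.
#' @param tags width-1 stranded tag `GRanges`.
#' @return `peaks` with `plus_intensity`/`minus_intensity` mcols set.
#' @export
peak_intensities <- function(peaks, tags) {
  std <- as.character(GenomicRanges::strand(tags))
  S4Vectors::mcols(peaks)$plus_intensity <-
    GenomicRanges::countOverlaps(peaks, tags[std == "+"], ignore.strand = TRUE)
  S4Vectors::mcols(peaks)$minus_intensity <-
    GenomicRanges::countOverlaps(peaks, tags[std == "-"], ignore.strand = TRUE)
  peaks
}

#' Cross-clone lesion-type concordance
#'
#' Calls are paired by >= 1 bp peak overlap (best overlap width when a call
#' matches several); the report gives the Pearson correlation of paired
#' log-ratios, the fraction of pairs with equal class, and the 2x2 class
#' contingency table.
#'
#' @param calls_a,calls_b classified peak `GRanges` (see
#'   [classify_lesions()]) from two clones on the same genome.
#' @return a `concordance_report`: list with `n_matched_pairs`, `pearson_r`
#'   (NA when undefined), `class_agreement`, `contingency`.
#' @export
concordance <- function(calls_a, calls_b) {
  hit <- GenomicRanges::findOverlaps(calls_a, calls_b, ignore.strand = TRUE)
  if (length(hit) == 0) {
    return(structure(list(n_matched_pairs = 0L, pearson_r = NA_real_,
                          class_agreement = NA_real_,
                          contingency = table(
                            factor(character(0), c("symmetric", "asymmetric")),
                            factor(character(0), c("symmetric", "asymmetric")))),
                     class = "concordance_report"))
  }
  ov <- GenomicRanges::width(IRanges::pintersect(
    calls_a[S4Vectors::queryHits(hit)], calls_b[S4Vectors::subjectHits(hit)],
    ignore.strand = TRUE))
  ## best-overlap partner per A call
  o <- order(S4Vectors::queryHits(hit), -ov)
  keep <- !duplicated(S4Vectors::queryHits(hit)[o])
  qa <- S4Vectors::queryHits(hit)[o][keep]
  sb <- S4Vectors::subjectHits(hit)[o][keep]
  lra <- calls_a$log_ratio[qa]; lrb <- calls_b$log_ratio[sb]
  r <- if (length(qa) >= 2 && stats::sd(lra) > 0 && stats::sd(lrb) > 0)
    stats::cor(lra, lrb) else NA_real_
  lev <- c("symmetric", "asymmetric")
  tab <- table(factor(calls_a$class[qa], lev), factor(calls_b$class[sb], lev))
  structure(list(n_matched_pairs = length(qa), pearson_r = r,
                 class_agreement = mean(calls_a$class[qa] == calls_b$class[sb]),
                 contingency = tab),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Cross-clone concordance:", x$n_matched_pairs, "matched pairs\n")
  cat("  Pearson r (log-ratios):", format(x$pearson_r, digits = 3), "\n")
  cat("  class agreement:", format(x$class_agreement, digits = 3), "\n")
  invisible(x)
}

#' Write lesion calls as TSV
#' @param calls classified peak `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lesion_calls <- function(calls, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(calls)),
                   start = GenomicRanges::start(calls) - 1L,
                   end = GenomicRanges::end(calls),
                   name = calls$name,
                   plus_intensity = calls$plus_intensity,
                   minus_intensity = calls$minus_intensity,
                   log_ratio = calls$log_ratio,
                   class = calls$class,
                   dominant_strand = calls$dominant_strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
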