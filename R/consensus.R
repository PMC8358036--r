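#' Replicate consensus by overlap (A-anchored)
#'
#' Returns the elements of `a` that overlap at least `min_overlap` bp with
#' some element of `b`, each reported once with `a`'s coordinates and
#' metadata (clone 1 by convention). With `merged = TRUE` the matched
#' A and B intervals are unioned into merged spans instead.
#'
#' @param a,b `GRanges` on the same genome.
#' @param min_overlap minimum overlap in bp (default 1).
#' @param merged return merged spans of the matched pairs instead of `a`'s
#'   coordinates.
#' @return `GRanges` consensus set.
#' @export
consensus_peaks <- function(a, b, min_overlap = 1, merged = FALSE) {
  hitn <- GenomicRanges::countOverlaps(a, b, minoverlap = min_overlap,
                                       ignore.strand = TRUE)
  if (!merged) return(a[hitn > 0])
  hit <- GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap,
                                     ignore.strand = TRUE)
  spans <- c(GenomicRanges::granges(a[unique(S4Vectors::queryHits(hit))]),
             GenomicRanges::granges(b[unique(S4Vectors::subjectHits(hit))]))
  GenomicRanges::reduce(spans, ignore.strand = TRUE)
}

#' Condition differencing: lost and gained peaks
#'
#' `lost` are untreated peaks with no treated overlap; `gained` are treated
#' peaks with no untreated overlap (each at the `min_overlap` threshold).
#'
#' @param untreated,treated `GRanges` peak sets on the same genome.
#' @param min_overlap minimum overlap in bp.
#' @return list with `lost` and `gained` `GRanges`.
#' @export
diff_condition <- function(untreated, treated, min_overlap = 1) {
  lost <- untreated[GenomicRanges::countOverlaps(
    untreated, treated, minoverlap = min_overlap, ignore.strand = TRUE) == 0]
  gained <- treated[GenomicRanges::countOverlaps(
    treated, untreated, minoverlap = min_overlap, ignore.strand = TRUE) == 0]
  list(lost = lost, gained = gained)
}

#' Difference sets shared across two clones
#'
#' Applies the A-anchored consensus to the two clones' lost (or gained)
#' sets: clone 1's peaks that are also lost (gained) in clone 2.
#'
#' @param clone1,clone2 `GRanges` difference sets from [diff_condition()].
#' @param min_overlap minimum overlap in bp.
#' @return `GRanges` shared set (clone-1 coordinates).
#' @export
shared_across_clones <- function(clone1, clone2, min_overlap = 1) {
  consensus_peaks(clone1, clone2, min_overlap = min_overlap)
}
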