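#' Score a simulated pipeline run against its ground truth
#'
#' Parameter-recovery metrics for a [run_pipeline()] report produced from a
#' simulation config: how many lesions shared by the first two clones are
#' recovered in the consensus set, how many consensus peaks match no planted
#' lesion, and how often the symmetric/asymmetric call agrees with the
#' planted class.
#'
#' A lesion counts as recovered when at least one consensus peak lies within
#' `match_window` bp of its position; a consensus peak is false when no
#' planted lesion (shared or not) lies within `match_window` of it. Class
#' accuracy is scored over consensus peaks matched to their nearest planted
#' lesion (DSB = symmetric, SSB = asymmetric).
#'
#' @param report a `run_report` from a simulation-mode [run_pipeline()] call.
#' @param match_window matching distance in bp; defaults to the simulation's
#'   `w_prox`.
#' @return list: `n_shared_lesions`, `recovery`, `false_fraction`,
#'   `n_matched_calls`, `class_accuracy`, `multi_peak_fraction` (shared
#'   lesions covered by more than one consensus peak).
#' @export
evaluate_run <- function(report, match_window = NULL) {
  st <- attr(report, "state")
  if (is.null(st$truth)) stop("report was not produced from a simulation run")
  truth <- st$truth
  if (is.null(match_window)) match_window <- truth$params$w_prox
  genome <- st$genome
  cons <- st$consensus

  inc1 <- lesion_inclusion(truth, 1)
  inc2 <- if (truth$params$n_replicates >= 2) lesion_inclusion(truth, 2)
  else inc1
  shared <- truth$lesions[inc1 & inc2, , drop = FALSE]
  sp <- GenomicRanges::GRanges(shared$chrom,
                               IRanges::IRanges(shared$pos, width = 1),
                               seqinfo = genome)
  hits_per_lesion <- GenomicRanges::countOverlaps(sp + match_window, cons,
                                                  ignore.strand = TRUE)
  recovery <- if (nrow(shared)) mean(hits_per_lesion > 0) else NA_real_

  allp <- GenomicRanges::GRanges(truth$lesions$chrom,
                                 IRanges::IRanges(truth$lesions$pos, width = 1),
                                 seqinfo = genome)
  false_fraction <- if (length(cons))
    mean(GenomicRanges::countOverlaps(cons + match_window, allp,
                                      ignore.strand = TRUE) == 0)
  else NA_real_

  ## class accuracy over consensus calls matched to their nearest lesion
  calls <- st$consensus_calls
  acc <- NA_real_; n_matched <- 0L
  if (length(calls) && nrow(truth$lesions)) {
    mid <- GenomicRanges::start(calls) +
      (GenomicRanges::width(calls) - 1L) %/% 2L
    cchr <- as.character(GenomicRanges::seqnames(calls))
    truth_cls <- ifelse(truth$lesions$class == "DSB",
                        "symmetric", "asymmetric")
    matched_cls <- vapply(seq_along(calls), function(i) {
      j <- which(truth$lesions$chrom == cchr[i])
      if (!length(j)) return(NA_character_)
      d <- abs(truth$lesions$pos[j] - mid[i])
      if (min(d) > match_window) return(NA_character_)
      truth_cls[j[which.min(d)]]
    }, character(1))
    ok <- !is.na(matched_cls)
    n_matched <- sum(ok)
    if (n_matched) acc <- mean(calls$class[ok] == matched_cls[ok])
  }

  list(n_shared_lesions = nrow(shared), recovery = recovery,
       false_fraction = false_fraction, n_matched_calls = n_matched,
       class_accuracy = acc,
       multi_peak_fraction = if (nrow(shared)) mean(hits_per_lesion > 1)
       else NA_real_)
}
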