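#' Run code with a temporary RNG seed
#'
#' Thin wrapper around [withr::with_seed()] so that every stochastic
#' operation in the package is scoped: the caller's RNG state is untouched
#' and identical seeds give identical results.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a finite integer")
  withr::with_seed(seed, code)
}

#' Derive a replicate-specific seed
#'
#' Replicate seeds are `seed XOR replicate_index`, so one top-level seed
#' reproduces every replicate while replicates stay independent.
#'
#' @param seed base integer seed.
#' @param index replicate index (non-negative integer).
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  s <- bitwXor(as.integer(seed), as.integer(index))
  # keep strictly below 2^31 and non-negative for set.seed()
  abs(s)
}

# small string hash (polynomial rolling hash mod a prime); used for
# stage-seed derivation and the config fingerprint in run reports.
str_hash32 <- function(x) {
  p <- 67108859
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% p
  as.integer(h)
}

#' Derive a stage-specific seed from the pipeline seed
#' @keywords internal
stage_seed <- function(seed, stage) {
  derive_seed(seed, str_hash32(stage))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
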