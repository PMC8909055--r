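# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves moving away from zero, the
#' convention used for the reported percentage tables (banker's rounding of
#' base `round()` would turn 0.5 into 0).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# stop() with a consistent prefix and no call
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Deterministic per-patient substream seed derived from one global seed, so a
# cohort can be extended without reshuffling earlier patients. Kept below
# 2^31 - 1.
substream_seed <- function(seed, i) {
  (abs(as.numeric(seed)) + 7919 * as.numeric(i)) %% 2147483647
}
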