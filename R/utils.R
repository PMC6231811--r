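`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up
#'
#' Base `round()` rounds half to even; reported percentages here use the
#' conventional half-up rule (e.g. 22.245 -> 22.25 at 2 decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon counters binary-representation error (0.145 * 10 < 1.45)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Truncate to a fixed number of decimals
#'
#' @param x numeric vector.
#' @param digits number of decimal places kept.
#' @return numeric vector truncated toward zero at `digits` decimals.
#' @export
trunc_to <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 1e-9) / p
}

# stop() without the call, with sprintf-style formatting
dv_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

dv_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
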