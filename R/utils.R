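#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals, as used
#' throughout survey reports: 0.25 -> 0.3 at one decimal, unlike base
#' [round()]'s round-half-to-even. A tiny epsilon absorbs binary
#' representation error so that values that are exactly `x.x5` in decimal
#' round upward.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1, the precision of the
#'   published tables this package works with).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.25, 0.35, 66.666), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# shared abort wrappers: every user-facing failure carries a class so callers
# and tests can distinguish configuration faults from data faults
abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "screenval_config_error", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "screenval_validation_error", ...)
}

abort_undefined <- function(msg, ...) {
  rlang::abort(msg, class = "screenval_undefined_error", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}
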