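#' False-negative-rate scenario
#'
#' Skip-rule routing gives a survey zero observed false negatives by
#' construction: screen-negatives never reach the full diagnostic module.
#' An external validation estimate of the screen's miss rate (here 2.4%,
#' from a clinical sample completing the module with no skip rules) can
#' be imposed after the fact: a fraction `rate` of the screen-negative
#' pool is assumed to be undetected true cases.
#'
#' @param rate assumed false-negative rate among screen-negatives, in
#'   [0, 1]. The two published scenarios are 0 (community) and 0.024
#'   (clinical).
#' @param rounding how the implied non-integer case count is rounded to
#'   whole subjects: `"half-up"` (default), `"floor"` or `"ceil"`.
#' @return a list of class `fn_scenario`.
#' @export
fn_scenario <- function(rate = 0, rounding = c("half-up", "floor", "ceil")) {
  rounding <- match.arg(rounding)
  if (!is_scalar_prob(rate)) abort_config("rate must be a probability")
  structure(list(rate = rate, rounding = rounding), class = "fn_scenario")
}

#' Reclassify screen-negatives under an assumed false-negative rate
#'
#' Moves `m = round(rate * (tn + fn))` subjects from true negatives to
#' false negatives; tp and fp are untouched, so PPV is invariant under
#' the adjustment while sensitivity, NPV, specificity and accuracy can
#' only fall. The rate applies to the whole screen-negative pool and the
#' imputed cases are drawn from tn, on top of any false negatives already
#' observed.
#'
#' @param table a [confusion_table()].
#' @param scenario an [fn_scenario()] (or a bare rate, taken with the
#'   default rounding).
#' @return the adjusted [confusion_table()]; cell total is conserved.
#'   If the implied count exceeds tn the scenario is infeasible and an
#'   error is raised.
#' @export
apply_fn_rate <- function(table, scenario = fn_scenario()) {
  if (!inherits(scenario, "fn_scenario")) scenario <- fn_scenario(scenario)
  pool <- table$tn + table$fn
  raw <- scenario$rate * pool
  m <- switch(scenario$rounding,
    "half-up" = round_half_up(raw, 0),
    "floor" = floor(raw),
    "ceil" = ceiling(raw)
  )
  if (m > table$tn) {
    abort_validation(paste0(
      "Infeasible scenario: ", m, " imputed cases exceed tn = ", table$tn
    ))
  }
  confusion_table(table$tp, table$fp, table$tn - m, table$fn + m)
}
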