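#' Project population prevalence from a screen-positive proportion
#'
#' When a survey wave administers only the screening items, the expected
#' prevalence of diagnosable disorder is estimated as the screen-positive
#' proportion times the positive predictive value established in an
#' earlier, fully verified wave; the PPV's 95% CI bounds give a crude
#' range. Sampling error in the screen-positive proportion itself is not
#' propagated — the range reflects PPV uncertainty only, and should be
#' read as indicative.
#'
#' @param screen_positive screen-positive proportion(s), percent scale.
#' @param ppv,ppv_lower,ppv_upper PPV point estimate and 95% CI bounds,
#'   percent scale.
#' @return a tibble with `estimate`, `lower`, `upper`: projected
#'   prevalence on the percent scale, unrounded (display convention is
#'   one decimal, half-up; see [round_half_up()]).
#' @examples
#' project_prevalence(13.0, 4.9, 1.9, 7.9)   # -> .6 (.2-1.0) at 1 dp
#' project_prevalence(58.2, 1.7, 0.9, 3.0)   # -> 1.0 (.5-1.7)
#' @export
project_prevalence <- function(screen_positive, ppv, ppv_lower = ppv,
                               ppv_upper = ppv) {
  vals <- c(screen_positive, ppv, ppv_lower, ppv_upper)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    abort_validation("All inputs must be percentages in [0, 100]")
  }
  if (any(ppv_lower > ppv) || any(ppv > ppv_upper)) {
    abort_validation("Need ppv_lower <= ppv <= ppv_upper")
  }
  tibble::tibble(
    estimate = screen_positive * ppv / 100,
    lower = screen_positive * ppv_lower / 100,
    upper = screen_positive * ppv_upper / 100
  )
}
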