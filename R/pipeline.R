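#' Run the full accuracy evaluation over a record set
#'
#' Orchestrates scoring, confusion-table construction and metric
#' estimation for every combination of age band, informant mode,
#' child-threshold variant, classification system and false-negative
#' scenario — the layout of the published accuracy tables (strata as
#' rows, five measures with 95% CIs as columns).
#'
#' @inheritParams validate_records
#' @param tau_child child/self-report threshold variants to evaluate
#'   (default `c(1, 2)`; the parent threshold stays at 2).
#' @param systems classification systems to evaluate.
#' @param fn_rates assumed false-negative rates among screen-negatives
#'   (default the two published scenarios, 0 and 0.024).
#' @param informants informant modes to evaluate.
#' @param alpha CI error rate.
#' @return a long tibble: one row per stratum x metric with `age_band`,
#'   `informant`, `tau_child`, `system`, `fn_rate`, the confusion cells,
#'   and `metric`, `k`, `n`, `point`, `lower`, `upper`, `method`
#'   (proportion scale; multiply by 100 and round half-up to one decimal
#'   for the printed layout, see [format_accuracy()]).
#' @export
run_study1 <- function(records,
                       tau_child = c(1L, 2L),
                       systems = c("dsm5", "icd10"),
                       fn_rates = c(0, 0.024),
                       informants = c("parent", "child", "combined"),
                       alpha = 0.05) {
  validate_records(records)
  grid <- expand.grid(
    age_band = intersect(AGE_BANDS, unique(records$age_band)),
    informant = informants, tau_child = tau_child, system = systems,
    fn_rate = fn_rates, stringsAsFactors = FALSE
  )
  out <- purrr::pmap(grid, function(age_band, informant, tau_child, system,
                                    fn_rate) {
    sub <- records[records$age_band == age_band, ]
    tab <- build_confusion(
      sub, informant = informant,
      policy = threshold_policy(tau_parent = 2L, tau_child = tau_child),
      system = system
    )
    tab <- apply_fn_rate(tab, fn_scenario(fn_rate))
    rep <- accuracy_report(tab, alpha = alpha)
    rep$age_band <- age_band
    rep$informant <- informant
    rep$tau_child <- tau_child
    rep$system <- system
    rep$fn_rate <- fn_rate
    rep$tp <- tab$tp; rep$fp <- tab$fp; rep$tn <- tab$tn; rep$fn <- tab$fn
    rep
  })
  front <- c("age_band", "informant", "tau_child", "system", "fn_rate")
  dplyr::bind_rows(out)[, c(front, "metric", "k", "n", "point", "lower",
                            "upper", "method", "tp", "fp", "tn", "fn")]
}

#' Project follow-up prevalence from published PPVs
#'
#' Maps each stratum of a screen-positive table to the matching published
#' PPV (parent-report rows for the 11-16 band, self-report rows for
#' 17-19) and multiplies through, giving the follow-up prevalence block:
#' estimate plus a range from the PPV's 95% CI.
#'
#' The PPV point estimate is invariant to the false-negative scenario
#' (the adjustment never touches tp or fp); its printed CI is not, and
#' `ppv_ci_source` selects which analysis the range is taken from. The
#' default `"fn-adjusted"` uses the 2.4%-scenario intervals.
#'
#' @param screen_positive tibble with `age_band`, `sex` and
#'   `screen_pos_2021` (percent), as from [mhcyp_screen_positive()]; an
#'   empty table yields an empty result.
#' @param metrics published metric rows as from
#'   [mhcyp_published_metrics()].
#' @param ppv_ci_source `"fn-adjusted"` (2.4% scenario) or `"zero-fn"`.
#' @param system classification system of the PPV rows used where the
#'   published strata distinguish them (the 17-19 rows do not).
#' @return a tibble: `age_band`, `sex`, `screen_positive`, `ppv`,
#'   `ppv_lower`, `ppv_upper` (inputs, percent), and rounded one-decimal
#'   `estimate`, `lower`, `upper` (projected prevalence, percent), plus
#'   unrounded `estimate_raw`, `lower_raw`, `upper_raw`.
#' @export
run_study2 <- function(screen_positive = mhcyp_screen_positive(),
                       metrics = mhcyp_published_metrics(),
                       ppv_ci_source = c("fn-adjusted", "zero-fn"),
                       system = "dsm5") {
  ppv_ci_source <- match.arg(ppv_ci_source)
  if (nrow(screen_positive) == 0) {
    return(screen_positive[, intersect(names(screen_positive),
                                       c("age_band", "sex"))])
  }
  ci_rate <- if (ppv_ci_source == "fn-adjusted") 0.024 else 0
  # reporting informant per band: parents report for 11-16, self for 17-19
  informant_for <- c("11-16" = "parent", "17-19" = "child")
  pick <- function(band, fn_rate) {
    inf <- unname(informant_for[band])
    if (is.na(inf)) return(NULL)
    rows <- metrics[
      metrics$age_band == band & metrics$informant == inf &
        metrics$tau_child == 1 & metrics$fn_rate == fn_rate &
        metrics$system %in% c(system, "both"),
    ]
    if (nrow(rows) == 0) NULL else rows[1, ]
  }
  out <- purrr::map(seq_len(nrow(screen_positive)), function(i) {
    band <- screen_positive$age_band[i]
    point_row <- pick(band, 0)
    ci_row <- pick(band, ci_rate)
    if (is.null(point_row) || is.null(ci_row)) {
      abort_config(paste0("No published PPV for stratum: age band ", band))
    }
    s <- screen_positive$screen_pos_2021[i]
    proj <- project_prevalence(s, point_row$ppv, ci_row$ppv_lower,
                               ci_row$ppv_upper)
    tibble::tibble(
      age_band = band,
      sex = screen_positive$sex[i],
      screen_positive = s,
      ppv = point_row$ppv,
      ppv_lower = ci_row$ppv_lower,
      ppv_upper = ci_row$ppv_upper,
      estimate = round_half_up(proj$estimate, 1),
      lower = round_half_up(proj$lower, 1),
      upper = round_half_up(proj$upper, 1),
      estimate_raw = proj$estimate,
      lower_raw = proj$lower,
      upper_raw = proj$upper
    )
  })
  dplyr::bind_rows(out)
}
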