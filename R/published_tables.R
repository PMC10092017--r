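#' Published 2017 accuracy metrics (built-in)
#'
#' The diagnostic-accuracy rows published from the 2017 survey: five
#' measures with 95% CI bounds, per informant stratum, classification
#' system, child-threshold variant and false-negative scenario. All
#' values are percentages rounded to one decimal exactly as printed;
#' CI cells printed as "(-)" are `NA`. These rows are the inputs to the
#' back-solve oracle and to the prevalence projection; the underlying
#' microdata are restricted.
#'
#' `system = "both"` marks 17-19 strata where the two classification
#' systems identified the same cases and a single row was published.
#'
#' @return a tibble, one row per published stratum: `fn_rate`,
#'   `tau_child`, `age_band`, `informant`, `system`, `n`, then
#'   `ppv`/`npv`/`sensitivity`/`specificity`/`accuracy` each with
#'   `_lower`/`_upper` CI columns.
#' @export
mhcyp_published_metrics <- function() {
  cols <- c(
    "fn_rate", "tau_child", "age_band", "informant", "system", "n",
    "ppv", "ppv_lower", "ppv_upper", "npv", "npv_lower", "npv_upper",
    "sensitivity", "sensitivity_lower", "sensitivity_upper",
    "specificity", "specificity_lower", "specificity_upper",
    "accuracy", "accuracy_lower", "accuracy_upper"
  )
  rows <- list(
    # zero false negatives, standard thresholds (parent 2+, child 1+)
    list(0, 1, "11-16", "parent", "dsm5", 3112, 4.9, 1.9, 7.9, 99.8, 99.6, 100.0, 66.7, 42.8, 90.5, 93.7, 92.8, 94.6, 93.6, 92.7, 94.5),
    list(0, 1, "11-16", "parent", "icd10", 3112, 4.4, 1.6, 7.2, 99.8, 99.6, 100.0, 64.3, 39.2, 89.4, 93.7, 92.8, 94.6, 93.6, 92.7, 94.5),
    list(0, 1, "11-16", "child", "dsm5", 2597, 1.0, 0.9, 1.1, 100.0, NA, NA, 100.0, 66.4, 100.0, 65.7, 63.4, 67.5, 65.8, 63.9, 67.6),
    list(0, 1, "11-16", "child", "icd10", 2597, 0.9, NA, NA, 100.0, NA, NA, 100.0, 63.1, 100.0, 65.6, 63.8, 67.5, 65.7, 63.9, 67.6),
    list(0, 1, "11-16", "combined", "dsm5", 2591, 0.8, 0.7, 0.8, 100.0, NA, NA, 100.0, 66.4, 100.0, 55.2, 53.3, 57.1, 55.4, 53.4, 57.3),
    list(0, 1, "11-16", "combined", "icd10", 2591, 0.7, 0.6, 0.7, 100.0, NA, NA, 100.0, 63.1, 100.0, 55.2, 53.2, 57.1, 55.3, 53.4, 57.2),
    list(0, 1, "17-19", "parent", "both", 415, 6.3, 4.5, 8.6, 100.0, NA, NA, 100.0, 15.8, 100.0, 92.7, 89.8, 95.1, 92.8, 89.8, 95.1),
    list(0, 1, "17-19", "child", "both", 935, 1.7, 1.6, 1.8, 100.0, NA, NA, 100.0, 59.0, 100.0, 55.3, 52.0, 58.5, 55.6, 52.4, 58.8),
    list(0, 1, "17-19", "combined", "both", 413, 0.9, 0.8, 1.0, 100.0, NA, NA, 100.0, 15.8, 100.0, 47.9, 43.0, 52.9, 48.2, 43.3, 53.1),
    # zero false negatives, child threshold raised to 2+
    list(0, 2, "11-16", "child", "dsm5", 2597, 1.9, 1.3, 2.6, 99.9, 99.7, 100.0, 77.8, 40.0, 97.2, 85.7, 84.3, 87.0, 85.6, 84.2, 87.0),
    list(0, 2, "11-16", "child", "icd10", 2597, 1.6, 1.1, 2.4, 99.9, 99.7, 100.0, 75.0, 34.9, 96.8, 85.6, 84.2, 87.0, 85.6, 84.2, 86.9),
    list(0, 2, "11-16", "combined", "dsm5", 2591, 2.4, 1.9, 3.1, 100.0, 99.7, 100.0, 88.9, 51.8, 99.7, 87.3, 86.0, 88.6, 87.3, 86.0, 88.6),
    list(0, 2, "11-16", "combined", "icd10", 2591, 2.1, 1.6, 2.8, 100.0, 99.7, 100.0, 87.5, 47.4, 99.7, 87.3, 86.0, 88.6, 87.3, 86.0, 88.6),
    list(0, 2, "17-19", "child", "both", 935, 3.8, 3.3, 4.3, 100.0, NA, NA, 100.0, 59.0, 100.0, 80.7, 78.0, 83.2, 80.8, 78.1, 83.3),
    list(0, 2, "17-19", "combined", "both", 413, 2.5, 2.1, 3.1, 100.0, NA, NA, 100.0, 15.8, 100.0, 81.3, 77.2, 84.9, 81.4, 77.3, 85.0),
    # 2.4% false-negative scenario, standard thresholds
    list(0.024, 1, "11-16", "parent", "dsm5", 3112, 4.9, 1.9, 7.9, 97.5, 96.8, 98.0, 11.8, 4.9, 18.6, 93.6, 92.7, 94.5, 91.4, 90.3, 92.3),
    list(0.024, 1, "11-16", "parent", "icd10", 3112, 4.4, 1.6, 7.2, 97.4, 96.8, 98.0, 10.7, 4.1, 17.3, 93.6, 92.7, 94.5, 91.3, 90.3, 92.3),
    list(0.024, 1, "11-16", "child", "dsm5", 2597, 1.0, 0.6, 1.8, 97.6, 97.3, 97.9, 18.0, 8.6, 31.4, 65.1, 63.2, 67.0, 64.2, 62.3, 66.0),
    list(0.024, 1, "11-16", "child", "icd10", 2597, 0.9, 0.5, 2.5, 97.6, 97.3, 97.9, 16.3, 7.3, 29.7, 65.1, 63.2, 66.9, 64.2, 62.3, 66.0),
    list(0.024, 1, "11-16", "combined", "dsm5", 2591, 0.8, 0.4, 1.4, 97.6, 97.2, 98.0, 20.9, 10.0, 36.0, 54.6, 52.6, 56.5, 54.0, 52.1, 56.0),
    list(0.024, 1, "11-16", "combined", "icd10", 2591, 0.7, 0.4, 1.3, 97.6, 97.2, 97.9, 19.1, 8.6, 34.1, 54.6, 52.6, 56.5, 54.0, 52.1, 55.9),
    list(0.024, 1, "17-19", "parent", "both", 415, 6.3, 1.8, 19.7, 97.7, 96.9, 98.2, 18.2, 2.3, 51.8, 92.6, 89.6, 94.9, 90.6, 87.4, 93.2),
    list(0.024, 1, "17-19", "child", "both", 935, 1.7, 0.9, 3.0, 97.7, 96.7, 98.3, 36.8, 16.3, 61.6, 54.7, 51.4, 58.0, 54.3, 51.1, 57.6),
    list(0.024, 1, "17-19", "combined", "both", 413, 0.9, 0.3, 2.9, 97.5, 96.0, 98.4, 28.6, 3.7, 71.0, 47.3, 42.4, 52.3, 47.0, 42.1, 51.9),
    # 2.4% false-negative scenario, child threshold 2+
    list(0.024, 2, "11-16", "child", "dsm5", 2597, 1.9, 0.9, 3.7, 97.5, 97.3, 97.7, 11.3, 4.7, 21.9, 85.4, 83.9, 86.7, 83.6, 82.1, 85.0),
    list(0.024, 2, "11-16", "child", "icd10", 2597, 1.6, 0.7, 3.4, 97.5, 97.3, 97.7, 9.8, 3.7, 20.2, 85.3, 83.9, 86.7, 83.6, 82.1, 85.0),
    list(0.024, 2, "11-16", "combined", "dsm5", 2591, 2.4, 1.3, 4.5, 97.6, 97.3, 97.8, 12.7, 5.7, 23.5, 87.1, 85.7, 88.4, 85.3, 83.8, 86.6),
    list(0.024, 2, "11-16", "combined", "icd10", 2591, 2.1, 1.0, 4.1, 97.6, 97.3, 97.8, 11.3, 4.7, 21.9, 87.0, 85.7, 88.3, 85.2, 83.8, 86.6),
    list(0.024, 2, "17-19", "child", "both", 935, 3.8, 2.0, 6.9, 97.6, 96.9, 98.1, 28.0, 12.1, 49.4, 80.3, 77.5, 82.8, 78.9, 76.1, 81.4),
    list(0.024, 2, "17-19", "combined", "both", 413, 2.5, 0.7, 8.4, 97.6, 96.8, 98.2, 20.0, 2.5, 55.6, 80.9, 76.7, 84.6, 79.4, 75.2, 83.2)
  )
  out <- tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    stats::setNames(as.data.frame(r, stringsAsFactors = FALSE), cols)
  })))
  out
}

#' Published screen-positive proportions and 2017 prevalence (built-in)
#'
#' Per-stratum screen-positive proportions from the 2017 survey and its
#' 2021 postal follow-up, with the 2017 clinician-rated prevalence. The
#' follow-up administered the screening items only, so its prevalence
#' must be projected via PPV. Reporting informant: parents for
#' 11-16-year-olds, self-report for 17-19-year-olds.
#'
#' @return a tibble with `age_band`, `report` (parent/self), `sex`,
#'   `screen_pos_2017`, `prevalence_2017`, `screen_pos_2021`, percent
#'   scale.
#' @export
mhcyp_screen_positive <- function() {
  tibble::tribble(
    ~age_band, ~report, ~sex, ~screen_pos_2017, ~prevalence_2017, ~screen_pos_2021,
    "11-16", "parent", "all",   6.5, 0.6, 13.0,
    "11-16", "parent", "girls", 8.4, 1.0, 17.8,
    "11-16", "parent", "boys",  5.1, 0.2, 8.4,
    "17-19", "self",  "all",   45.1, 0.8, 58.2,
    "17-19", "self",  "girls", 60.5, 1.6, 76.4,
    "17-19", "self",  "boys",  29.6, 0.0, 41.0
  )
}
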