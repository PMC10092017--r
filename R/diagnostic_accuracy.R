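#' Construct a 2x2 confusion table
#'
#' @param tp,fp,tn,fn non-negative integer cell counts (index test vs
#'   reference standard).
#' @return a list of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    abort_validation("Confusion-table cells must be non-negative integers")
  }
  structure(as.list(stats::setNames(as.integer(cells), names(cells))),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("screen+", "screen-"), c("case", "non-case")))
  print(m)
  invisible(x)
}

#' Build a confusion table from scored survey records
#'
#' The index test is the screen decision for the chosen informant mode;
#' the reference standard is the clinician diagnosis under the chosen
#' classification system. Under the survey's skip-rule routing only
#' screen-positives (by the combined rule) received the full diagnostic
#' module, so an unverified subject carries no diagnosis and counts as
#' reference-negative. False negatives for a *single-informant* index are
#' still possible: the other informant's screen can trigger verification
#' of a subject the indexed informant missed.
#'
#' @inheritParams validate_records
#' @param informant index-test informant: `"parent"`, `"child"` or
#'   `"combined"`.
#' @param policy a [threshold_policy()]; its combination rule is
#'   overridden by `informant`.
#' @param system reference classification, `"dsm5"` or `"icd10"`.
#' @param include_singletons for `informant = "combined"`, keep subjects
#'   with only one reporting informant (default `FALSE`: restrict to
#'   complete dyads, the convention of the published combined strata).
#' @return a [confusion_table()]. Scope: subjects with the indexed
#'   informant present (both, for combined with `include_singletons =
#'   FALSE`).
#' @export
build_confusion <- function(records,
                            informant = c("parent", "child", "combined"),
                            policy = threshold_policy(),
                            system = c("dsm5", "icd10"),
                            include_singletons = FALSE) {
  informant <- match.arg(informant)
  system <- match.arg(system)
  if (nrow(records) == 0) abort_validation("Empty record set")
  validate_records(records)
  scored <- score_records(records, threshold_policy(
    policy$tau_parent, policy$tau_child, "either-positive"
  ))
  scope <- switch(informant,
    parent = scored$parent_present,
    child = scored$child_present,
    combined = if (include_singletons) {
      scored$parent_present | scored$child_present
    } else {
      scored$parent_present & scored$child_present
    }
  )
  sub <- scored[scope, ]
  if (nrow(sub) == 0) abort_validation("No records in scope for this mode")
  index_pos <- switch(informant,
    parent = sub$parent_pos,
    child = sub$child_pos,
    combined = combine_screens(sub$parent_pos, sub$child_pos,
                               "either-positive")
  )
  dx <- sub[[paste0("dx_", system)]]
  ref_pos <- !is.na(dx) & dx  # absent dx => reference-negative (routing)
  confusion_table(
    tp = sum(index_pos & ref_pos),
    fp = sum(index_pos & !ref_pos),
    tn = sum(!index_pos & !ref_pos),
    fn = sum(!index_pos & ref_pos)
  )
}

#' Metric numerator and denominator from a confusion table
#'
#' The five accuracy measures as count pairs: sensitivity tp/(tp+fn),
#' specificity tn/(tn+fp), PPV tp/(tp+fp), NPV tn/(tn+fn), accuracy
#' (tp+tn)/n.
#'
#' @param table a [confusion_table()].
#' @param which one of `"se"`, `"sp"`, `"ppv"`, `"npv"`, `"acc"`.
#' @return a list with integer `k` and `n`. A zero denominator raises a
#'   `screenval_undefined_error` (rendered "(-)" in formatted tables).
#' @export
metric_counts <- function(table, which = c("se", "sp", "ppv", "npv", "acc")) {
  which <- match.arg(which)
  kn <- switch(which,
    se  = c(table$tp, table$tp + table$fn),
    sp  = c(table$tn, table$tn + table$fp),
    ppv = c(table$tp, table$tp + table$fp),
    npv = c(table$tn, table$tn + table$fn),
    acc = c(table$tp + table$tn, table$tp + table$fp + table$tn + table$fn)
  )
  if (kn[2] == 0) {
    abort_undefined(paste0("Metric ", which, " undefined: zero denominator"))
  }
  list(k = kn[1], n = kn[2])
}

#' Wald (normal-approximation) binomial confidence interval
#'
#' p +/- z * sqrt(p(1-p)/n), truncated to [0, 1].
#'
#' @param k,n successes and trials, `n > 0`.
#' @param alpha two-sided error rate (default 0.05 for 95% intervals).
#' @return `c(lower, upper)` on the proportion scale.
#' @export
wald_ci <- function(k, n, alpha = 0.05) {
  if (n <= 0) abort_undefined("Wald interval needs n > 0")
  p <- k / n
  half <- stats::qnorm(1 - alpha / 2) * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form; at k = n the lower bound is (alpha/2)^(1/n) and
#' the upper bound 1, mirrored at k = 0.
#'
#' @inheritParams wald_ci
#' @return `c(lower, upper)` on the proportion scale.
#' @export
exact_ci <- function(k, n, alpha = 0.05) {
  if (n <= 0) abort_undefined("Exact interval needs n > 0")
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower, upper)
}

#' Proportion with confidence interval
#'
#' The package's interval policy (`method = "auto"`, the default used for
#' all reporting) is Wald for interior proportions with an exact
#' Clopper-Pearson fallback at the boundary (k = 0 or k = n), where the
#' Wald interval degenerates to a point.
#'
#' @inheritParams wald_ci
#' @param method `"auto"`, `"wald"` or `"exact"`.
#' @return a tibble row: `k`, `n`, `point`, `lower`, `upper`, `method`
#'   (all on the proportion scale; `method` records the interval actually
#'   used, `"degenerate"` when n = 0).
#' @export
proportion_estimate <- function(k, n, alpha = 0.05,
                                method = c("auto", "wald", "exact")) {
  method <- match.arg(method)
  if (n == 0) {
    return(tibble::tibble(k = 0L, n = 0L, point = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          method = "degenerate"))
  }
  if (k < 0 || k > n) abort_validation("Need 0 <= k <= n")
  used <- if (method == "auto") {
    if (k == 0 || k == n) "exact" else "wald"
  } else {
    method
  }
  ci <- if (used == "wald") wald_ci(k, n, alpha) else exact_ci(k, n, alpha)
  tibble::tibble(
    k = as.integer(k), n = as.integer(n), point = k / n,
    lower = ci[1], upper = ci[2], method = used
  )
}

#' Full accuracy report for a confusion table
#'
#' Computes the five measures with confidence intervals under the
#' package's CI policy. Zero-denominator measures are kept in the output
#' with `NA` values and `method = "degenerate"` so strata render as "(-)".
#'
#' @param table a [confusion_table()].
#' @param alpha two-sided error rate for the intervals.
#' @param method CI policy passed to [proportion_estimate()].
#' @param stratum optional stratum label carried into the output.
#' @return a tibble with one row per metric (`metric`, `k`, `n`, `point`,
#'   `lower`, `upper`, `method`, plus `stratum` when given), proportions
#'   on the [0, 1] scale.
#' @export
accuracy_report <- function(table, alpha = 0.05, method = "auto",
                            stratum = NULL) {
  rows <- lapply(c("se", "sp", "ppv", "npv", "acc"), function(w) {
    kn <- tryCatch(metric_counts(table, w),
                   screenval_undefined_error = function(e) list(k = 0L, n = 0L))
    est <- proportion_estimate(kn$k, kn$n, alpha, method)
    est$metric <- w
    est
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("metric", "k", "n", "point", "lower", "upper", "method")]
  if (!is.null(stratum)) out$stratum <- stratum
  out
}

#' Render an accuracy report as printed percentages
#'
#' One-decimal half-up percentages in the "point (lower-upper)" style of
#' published accuracy tables; undefined cells render as `"(-)"`.
#'
#' @param report output of [accuracy_report()].
#' @return a tibble with `metric` and a formatted `display` string.
#' @export
format_accuracy <- function(report) {
  fmt1 <- function(x) formatC(round_half_up(100 * x, 1), format = "f", digits = 1)
  disp <- ifelse(
    report$method == "degenerate",
    "(-)",
    paste0(fmt1(report$point), " (", fmt1(report$lower), "-",
           fmt1(report$upper), ")")
  )
  tibble::tibble(metric = report$metric, display = disp)
}

#' Pooled-variance two-sample t-test on two sets of metric percentages
#'
#' Used to compare accuracy profiles between classification systems
#' (e.g. DSM-5 vs ICD-10 columns of a published table). Classical
#' equal-variance two-sample t with df = n_a + n_b - 2.
#'
#' @param a,b numeric vectors of percentages (non-empty).
#' @return a list with `t`, `df` and `p`.
#' @export
compare_metric_sets <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort_config("Each metric set needs at least two values")
  }
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled == 0) {
    abort_undefined("Zero pooled variance: t statistic undefined")
  }
  fit <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}
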