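#' Back-solve integer confusion-table cells from published rounded metrics
#'
#' Published accuracy tables print one-decimal percentages and a stratum
#' size; when the microdata are restricted, the integer 2x2 cells can
#' often be recovered exactly by exhaustive search over non-negative
#' (tp, fp, tn, fn) whose total is within `n_tolerance` of the printed n
#' and whose metrics, rounded half-up to one decimal, equal every printed
#' value supplied. Printed confidence-interval bounds, where supplied,
#' act as additional filters under the package's CI policy ([wald_ci()]
#' for interior proportions, [exact_ci()] at the boundary) — a boundary
#' sensitivity CI pins down the exact case count, since the exact lower
#' bound at k = n is (alpha/2)^(1/n).
#'
#' The search is pruned by deriving the tp+fp range from PPV and the
#' tp+fn range from sensitivity before enumeration, so rows with n in the
#' thousands solve in well under a second.
#'
#' @param n printed stratum size (positive integer, capped at 1e5).
#' @param ppv,npv,sensitivity,specificity,accuracy printed one-decimal
#'   percentages; `NULL` for values not printed. At least three of the
#'   five must be supplied.
#' @param ci optional named list of printed CI bounds to filter on, e.g.
#'   `list(sensitivity = c(15.8, 100.0), ppv = c(1.9, 7.9))` (percent
#'   scale, one decimal).
#' @param n_tolerance allowed |cell total - n| (default 3: printed n may
#'   include subjects excluded from the metric denominators).
#' @param alpha error rate for the CI filters.
#' @return a tibble of all solutions (columns tp, fp, tn, fn), possibly
#'   empty, possibly several rows.
#' @export
backsolve_cells <- function(n, ppv = NULL, npv = NULL, sensitivity = NULL,
                            specificity = NULL, accuracy = NULL,
                            ci = list(), n_tolerance = 3, alpha = 0.05) {
  if (n > 1e5) abort_config("Search capped at n = 1e5")
  if (n < 1 || n != floor(n)) abort_config("n must be a positive integer")
  metrics <- list(ppv = ppv, npv = npv, se = sensitivity,
                  sp = specificity, acc = accuracy)
  if (sum(!vapply(metrics, is.null, logical(1))) < 3) {
    abort_config("Back-solving needs at least three printed metrics")
  }
  names(ci) <- sub("^sensitivity$", "se", sub("^specificity$", "sp", names(ci)))

  # inclusive integer range of numerators k with round(100*k/d) == pct,
  # over-inclusive at the edges; exact rounding is re-checked later
  k_range <- function(d, pct) {
    lo <- max(0L, floor(d * (pct - 0.051) / 100))
    hi <- min(d, ceiling(d * (pct + 0.051) / 100))
    if (lo > hi) integer(0) else lo:hi
  }
  rounds_to <- function(k, d, pct) {
    round_half_up(100 * k / d, 1) == pct
  }
  ci_ok <- function(k, d, bounds) {
    est <- proportion_estimate(k, d, alpha, "auto")
    identical(round_half_up(100 * c(est$lower, est$upper), 1),
              as.numeric(bounds))
  }

  sols <- list()
  for (total in max(1, n - n_tolerance):(n + n_tolerance)) {
    for (pos in 0:total) {
      tp_cands <- if (!is.null(metrics$ppv)) {
        if (pos == 0) 0L else k_range(pos, metrics$ppv)
      } else 0:pos
      for (tp in tp_cands) {
        fp <- pos - tp
        neg <- total - pos
        fn_cands <- if (!is.null(metrics$se)) {
          if (metrics$se == 0 && tp > 0) next
          if (tp == 0) {
            # se printed > 0 impossible with tp = 0 unless denominator 0
            if (metrics$se > 0) 0L else 0:neg
          } else {
            d_lo <- max(tp, floor(100 * tp / (metrics$se + 0.051)))
            d_hi <- if (metrics$se <= 0.05) neg + tp else
              ceiling(100 * tp / max(metrics$se - 0.051, 1e-9))
            lo_fn <- max(0, d_lo - tp)
            hi_fn <- min(neg, d_hi - tp)
            if (lo_fn > hi_fn) next
            lo_fn:hi_fn
          }
        } else 0:neg
        for (fn in fn_cands) {
          if (fn < 0 || fn > neg) next
          tn <- neg - fn
          ok <- TRUE
          pairs <- list(
            ppv = c(tp, pos), npv = c(tn, tn + fn),
            se = c(tp, tp + fn), sp = c(tn, tn + fp), acc = c(tp + tn, total)
          )
          for (w in names(metrics)) {
            if (is.null(metrics[[w]])) next
            kd <- pairs[[w]]
            if (kd[2] == 0 || !rounds_to(kd[1], kd[2], metrics[[w]])) {
              ok <- FALSE; break
            }
          }
          if (!ok) next
          for (w in names(ci)) {
            kd <- pairs[[w]]
            if (kd[2] == 0 || !ci_ok(kd[1], kd[2], ci[[w]])) {
              ok <- FALSE; break
            }
          }
          if (!ok) next
          sols[[length(sols) + 1]] <- c(tp = tp, fp = fp, tn = tn, fn = fn)
        }
      }
    }
  }
  out <- if (length(sols) == 0) {
    tibble::tibble(tp = integer(0), fp = integer(0),
                   tn = integer(0), fn = integer(0))
  } else {
    tibble::as_tibble(do.call(rbind, sols))
  }
  dplyr::distinct(out)
}
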