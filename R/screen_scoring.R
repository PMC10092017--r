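#' Threshold policy for the five-item screen
#'
#' The screen is scored per informant by counting endorsed ("yes") items;
#' an informant screens positive when the count reaches their threshold.
#' The standard operating point uses two endorsed items for parents and
#' one for children or young people (the lower threshold reflecting how
#' readily young people conceal eating difficulties); a common variant
#' raises the child threshold to two. Informants are combined with an
#' either-positive (logical OR) rule: the dyad screens positive if any
#' reporting informant does.
#'
#' @param tau_parent parent threshold, integer in 1..5 (default 2).
#' @param tau_child child/self-report threshold, integer in 1..5
#'   (default 1; the variant uses 2).
#' @param combination how informants combine: `"either-positive"`,
#'   `"parent-only"` or `"child-only"`.
#' @return a list of class `threshold_policy`.
#' @export
threshold_policy <- function(tau_parent = 2L, tau_child = 1L,
                             combination = c("either-positive", "parent-only",
                                             "child-only")) {
  combination <- match.arg(combination)
  for (tau in c(tau_parent, tau_child)) {
    if (!is.numeric(tau) || length(tau) != 1 || tau < 1 || tau > 5 ||
        tau != floor(tau)) {
      abort_config("Thresholds must be integers between 1 and 5")
    }
  }
  structure(
    list(tau_parent = as.integer(tau_parent),
         tau_child = as.integer(tau_child),
         combination = combination),
    class = "threshold_policy"
  )
}

#' Score a five-item screen response
#'
#' Counts endorsed items and applies a threshold. A skipped item (NA)
#' counts toward neither the endorsement count nor the answered count:
#' missing scores as "no", conservative toward screen-negative. With
#' `strict = TRUE` a response with any skipped item is rejected instead.
#'
#' @param items integer/logical vector of exactly five items (1/0/NA), or
#'   a matrix with five columns to score many responses at once.
#' @param tau threshold, integer in 1..5.
#' @param strict reject responses containing a skipped item?
#' @return a tibble with columns `k` (endorsed count), `n_answered`
#'   (non-missing items) and `positive` (`k >= tau`); one row per
#'   response.
#' @examples
#' score_items(c(1, 0, 0, 0, 0), tau = 2)  # parent standard: negative
#' score_items(c(1, 0, 0, 0, 0), tau = 1)  # child standard: positive
#' @export
score_items <- function(items, tau, strict = FALSE) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  if (ncol(items) != 5) {
    abort_validation("A screen response has exactly five items")
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau < 1 || tau > 5) {
    abort_config("tau must lie in 1..5")
  }
  storage.mode(items) <- "integer"
  n_answered <- rowSums(!is.na(items))
  if (strict && any(n_answered < 5)) {
    abort_validation("Response with skipped item(s) rejected in strict mode")
  }
  k <- rowSums(items == 1L, na.rm = TRUE)
  tibble::tibble(
    k = as.integer(k),
    n_answered = as.integer(n_answered),
    positive = k >= tau
  )
}

#' Combine informant screen decisions
#'
#' @param parent_positive,child_positive logical vectors; `NA` marks an
#'   absent informant (no response at all, not a negative screen).
#' @param rule combination rule as in [threshold_policy()].
#' @return logical vector of combined decisions. Under either-positive an
#'   absent informant is ignored; a subject with neither informant is an
#'   error, as is a missing required informant under a single-informant
#'   rule.
#' @export
combine_screens <- function(parent_positive, child_positive,
                            rule = c("either-positive", "parent-only",
                                     "child-only")) {
  rule <- match.arg(rule)
  n <- max(length(parent_positive), length(child_positive))
  parent_positive <- rep_len(parent_positive, n)
  child_positive <- rep_len(child_positive, n)
  switch(rule,
    "either-positive" = {
      if (any(is.na(parent_positive) & is.na(child_positive))) {
        abort_undefined("Subject with no informant decision to combine")
      }
      p <- !is.na(parent_positive) & parent_positive
      c <- !is.na(child_positive) & child_positive
      p | c
    },
    "parent-only" = {
      if (any(is.na(parent_positive))) {
        abort_undefined("parent-only rule requires a parent decision")
      }
      parent_positive
    },
    "child-only" = {
      if (any(is.na(child_positive))) {
        abort_undefined("child-only rule requires a child decision")
      }
      child_positive
    }
  )
}

#' Score a record table under a threshold policy
#'
#' Adds per-informant scores and the combined screen decision to a
#' subject-record table.
#'
#' @inheritParams validate_records
#' @param policy a [threshold_policy()].
#' @return `records` with added columns `parent_k`, `parent_pos`,
#'   `child_k`, `child_pos` (NA where the informant is absent) and
#'   `screen_pos` (the policy's combined decision; NA only when the
#'   combination rule's required informant is absent).
#' @export
score_records <- function(records, policy = threshold_policy()) {
  validate_records(records)
  pq <- as.matrix(records[paste0("parent_q", 1:5)])
  cq <- as.matrix(records[paste0("child_q", 1:5)])
  ps <- score_items(pq, policy$tau_parent)
  cs <- score_items(cq, policy$tau_child)
  records$parent_k <- ifelse(records$parent_present, ps$k, NA_integer_)
  records$parent_pos <- ifelse(records$parent_present, ps$positive, NA)
  records$child_k <- ifelse(records$child_present, cs$k, NA_integer_)
  records$child_pos <- ifelse(records$child_present, cs$positive, NA)
  records$screen_pos <- switch(policy$combination,
    "either-positive" = combine_screens(records$parent_pos, records$child_pos,
                                        "either-positive"),
    "parent-only" = ifelse(records$parent_present, records$parent_pos, NA),
    "child-only" = ifelse(records$child_present, records$child_pos, NA)
  )
  records
}
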