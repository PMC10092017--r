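#' Configuration for the synthetic survey generator
#'
#' Defines a two-age-band population (11-16 with parent-led reporting,
#' 17-19 with self-led reporting) in which a latent disorder of low
#' prevalence drives endorsement of five binary screening items per
#' reporting informant. Items are conditionally independent Bernoulli
#' draws given disorder status, and parent and child responses are
#' independent given status; an `informant_correlation` slot is reserved
#' but any nonzero value is rejected, since correlated informants are
#' deliberately not modelled.
#'
#' The shipped defaults ("mhcyp2017-like") target the operating point of
#' the 2017 national survey: band sizes 3118 and 937 (approx. 4055
#' subjects aged 11-19), prevalence 0.6% / 0.8%, control-item rates
#' solved so that approx. 6.5% of parents of 11-16-year-olds, 34% of
#' 11-16-year-old children and 45% of 17-19-year-olds screen positive at
#' the standard thresholds, and informant availability matching the
#' published stratum sizes (3112 parents, 2597 children, 2591 complete
#' dyads in the younger band).
#'
#' @param n subjects per age band (named by band, or a scalar for both).
#' @param prevalence latent disorder prevalence per band, in [0, 1].
#' @param p_parent_present,p_child_present probability each informant
#'   provides a response (subjects with neither are dropped).
#' @param q_case_parent,q_case_child,q_ctrl_parent,q_ctrl_child per-item
#'   endorsement probability given disorder (case) or not (ctrl); each
#'   may be a scalar, a vector named by band, or a list per band of five
#'   per-item probabilities.
#' @param ref_fn_rate probability that a verified true case is still
#'   rated non-case by the reference standard (0 for the community
#'   scenario, 0.024 for the clinical one).
#' @param informant_correlation must be 0 (reserved).
#' @param seed integer seed; generation is fully reproducible from it.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = c("11-16" = 3118, "17-19" = 937),
                             prevalence = c("11-16" = 0.006, "17-19" = 0.008),
                             p_parent_present = c("11-16" = 0.998,
                                                  "17-19" = 0.443),
                             p_child_present = c("11-16" = 0.833,
                                                 "17-19" = 0.998),
                             q_case_parent = 0.40,
                             q_case_child = c("11-16" = 0.60, "17-19" = 0.65),
                             q_ctrl_parent = c("11-16" = 0.088,
                                               "17-19" = 0.097),
                             q_ctrl_child = c("11-16" = 0.080,
                                              "17-19" = 0.113),
                             ref_fn_rate = 0,
                             informant_correlation = 0,
                             seed = 8467L) {
  if (!identical(as.numeric(informant_correlation), 0)) {
    abort_config("Correlated informants are not modelled; correlation must be 0")
  }
  if (!is_scalar_prob(ref_fn_rate)) {
    abort_config("ref_fn_rate must be a probability")
  }
  per_band_scalar <- function(x, what, integerish = FALSE) {
    if (length(x) == 1 && is.null(names(x))) {
      x <- stats::setNames(rep(x, 2), AGE_BANDS)
    }
    if (!all(AGE_BANDS %in% names(x))) {
      abort_config(paste0(what, " must cover both age bands"))
    }
    x <- x[AGE_BANDS]
    if (integerish) {
      if (any(x < 1 | x != floor(x))) abort_config(paste0(what, " must be >= 1"))
    } else if (any(x < 0 | x > 1)) {
      abort_config(paste0(what, " must lie in [0, 1]"))
    }
    x
  }
  # item probabilities: scalar, band-named vector, or per-band list of 5
  per_band_items <- function(x, what) {
    if (is.list(x)) {
      if (!all(AGE_BANDS %in% names(x))) {
        abort_config(paste0(what, " list must be named by age band"))
      }
      out <- lapply(x[AGE_BANDS], function(v) {
        v <- if (length(v) == 1) rep(v, 5) else v
        if (length(v) != 5 || any(v < 0 | v > 1)) {
          abort_config(paste0(what, " needs five probabilities per band"))
        }
        v
      })
      return(out)
    }
    sc <- per_band_scalar(x, what)
    lapply(stats::setNames(AGE_BANDS, AGE_BANDS), function(b) rep(sc[[b]], 5))
  }
  structure(list(
    n = per_band_scalar(n, "n", integerish = TRUE),
    prevalence = per_band_scalar(prevalence, "prevalence"),
    p_parent_present = per_band_scalar(p_parent_present, "p_parent_present"),
    p_child_present = per_band_scalar(p_child_present, "p_child_present"),
    q = list(
      case = list(parent = per_band_items(q_case_parent, "q_case_parent"),
                  child = per_band_items(q_case_child, "q_case_child")),
      ctrl = list(parent = per_band_items(q_ctrl_parent, "q_ctrl_parent"),
                  child = per_band_items(q_ctrl_child, "q_ctrl_child"))
    ),
    ref_fn_rate = ref_fn_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic screening survey
#'
#' Draws subject records under a [synthetic_config()]: latent disorder
#' status, informant availability, five conditionally independent
#' Bernoulli items per present informant, then the verification stage.
#' Under `verification = "routing"` (the survey design) the full
#' diagnostic module is administered exactly to subjects screening
#' positive under the either-positive rule at the standard thresholds,
#' so screen-negatives carry no diagnosis; `"complete"` administers it
#' to everyone, as in a validation study with skip rules disabled.
#' A verified true case is rated non-case with probability
#' `ref_fn_rate`; both classification systems are simulated as rating
#' the same cases.
#'
#' @param config a [synthetic_config()].
#' @param verification `"routing"` or `"complete"`.
#' @param policy [threshold_policy()] used for the routing decision.
#' @return a record tibble as in [read_records()], plus a `disorder`
#'   column holding the latent simulation truth (not part of the record
#'   model; [write_records()] drops it).
#' @export
generate_survey <- function(config, verification = c("routing", "complete"),
                            policy = threshold_policy()) {
  verification <- match.arg(verification)
  if (!inherits(config, "synthetic_config")) {
    abort_config("config must be a synthetic_config")
  }
  withr::with_seed(config$seed, {
    bands <- lapply(AGE_BANDS, function(band) {
      n <- config$n[[band]]
      disorder <- stats::runif(n) < config$prevalence[[band]]
      parent_present <- stats::runif(n) < config$p_parent_present[[band]]
      child_present <- stats::runif(n) < config$p_child_present[[band]]
      draw_items <- function(who) {
        qc <- config$q$case[[who]][[band]]
        q0 <- config$q$ctrl[[who]][[band]]
        probs <- matrix(rep(ifelse(disorder, 1, 0), 5), n, 5)
        probs <- probs * matrix(qc, n, 5, byrow = TRUE) +
          (1 - probs) * matrix(q0, n, 5, byrow = TRUE)
        items <- matrix(
          as.integer(stats::runif(5L * n) < probs), n, 5
        )
        present <- if (who == "parent") parent_present else child_present
        items[!present, ] <- NA_integer_
        items
      }
      pq <- draw_items("parent")
      cq <- draw_items("child")
      flip <- stats::runif(n) < config$ref_fn_rate
      tibble::tibble(
        subject_id = paste0("S", band, "-", sprintf("%05d", seq_len(n))),
        age_band = band,
        parent_present = parent_present,
        parent_q1 = pq[, 1], parent_q2 = pq[, 2], parent_q3 = pq[, 3],
        parent_q4 = pq[, 4], parent_q5 = pq[, 5],
        child_present = child_present,
        child_q1 = cq[, 1], child_q2 = cq[, 2], child_q3 = cq[, 3],
        child_q4 = cq[, 4], child_q5 = cq[, 5],
        disorder = disorder,
        .flip = flip
      )
    })
    records <- dplyr::bind_rows(bands)
  })
  records <- records[records$parent_present | records$child_present, ]
  if (verification == "routing") {
    # verified iff screen-positive under the either-positive routing rule
    pq <- as.matrix(records[paste0("parent_q", 1:5)])
    cq <- as.matrix(records[paste0("child_q", 1:5)])
    ppos <- ifelse(records$parent_present,
                   score_items(pq, policy$tau_parent)$positive, NA)
    cpos <- ifelse(records$child_present,
                   score_items(cq, policy$tau_child)$positive, NA)
    records$verified <- combine_screens(ppos, cpos, "either-positive")
  } else {
    records$verified <- TRUE
  }
  dx <- ifelse(records$verified, records$disorder & !records$.flip, NA)
  records$dx_dsm5 <- dx
  records$dx_icd10 <- dx
  records$.flip <- NULL
  validate_records(records)
  records
}

# P(sum of independent Bernoulli(q_i) >= tau), q a length-5 vector
poibin_tail <- function(q, tau) {
  pmf <- 1
  for (qi in q) pmf <- c(pmf * (1 - qi), 0) + c(0, pmf * qi)
  sum(pmf[(tau + 1):length(pmf)])
}

#' Closed-form accuracy of the synthetic screen
#'
#' Analytic expectation of the accuracy measures under a
#' [synthetic_config()], against the latent disorder status as reference
#' (i.e. complete verification and a perfect reference standard,
#' `ref_fn_rate = 0`). Per-informant positivity is the Poisson-binomial
#' tail P(endorsed >= tau | status) over the five item probabilities;
#' the either-positive combination uses conditional independence of
#' informants given status; PPV and NPV follow from Bayes' rule at the
#' band's prevalence.
#'
#' @param config a [synthetic_config()].
#' @param informant `"parent"`, `"child"` or `"combined"`.
#' @param age_band `"11-16"` or `"17-19"`.
#' @param policy [threshold_policy()] giving the thresholds.
#' @return a named list: `se`, `sp`, `ppv`, `npv`, `acc`,
#'   `p_screen_positive` (marginal), proportions in [0, 1].
#' @export
closed_form_metrics <- function(config,
                                informant = c("parent", "child", "combined"),
                                age_band = "11-16",
                                policy = threshold_policy()) {
  informant <- match.arg(informant)
  if (!age_band %in% AGE_BANDS) abort_config("Unknown age band")
  pos_prob <- function(status) {
    pp <- poibin_tail(config$q[[status]]$parent[[age_band]], policy$tau_parent)
    pc <- poibin_tail(config$q[[status]]$child[[age_band]], policy$tau_child)
    switch(informant,
      parent = pp,
      child = pc,
      combined = 1 - (1 - pp) * (1 - pc)
    )
  }
  pi_b <- config$prevalence[[age_band]]
  se <- pos_prob("case")
  sp <- 1 - pos_prob("ctrl")
  p_pos <- pi_b * se + (1 - pi_b) * (1 - sp)
  list(
    se = se,
    sp = sp,
    ppv = if (p_pos > 0) pi_b * se / p_pos else NA_real_,
    npv = if (p_pos < 1) (1 - pi_b) * sp / (1 - p_pos) else NA_real_,
    acc = pi_b * se + (1 - pi_b) * sp,
    p_screen_positive = p_pos
  )
}
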