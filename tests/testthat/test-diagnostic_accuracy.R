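test_that("metric counts follow the 2x2 definitions", {
  sym <- confusion_table(1, 1, 1, 1)
  for (w in c("se", "sp", "ppv", "npv", "acc")) {
    kn <- metric_counts(sym, w)
    expect_equal(kn$k / kn$n, 0.5)
  }
  t1 <- confusion_table(2, 30, 381, 0)
  expect_equal(round_half_up(100 * 2 / 32), 6.3)
  expect_equal(with(metric_counts(t1, "ppv"), c(k, n)), c(2, 32))
  expect_equal(with(metric_counts(t1, "acc"), c(k, n)), c(383, 413))
  expect_equal(round_half_up(100 * 383 / 413), 92.7)

  t2 <- confusion_table(7, 415, 513, 0)
  expect_equal(with(metric_counts(t2, "sp"), c(k, n)), c(513, 928))
  expect_equal(round_half_up(100 * 513 / 928), 55.3)

  expect_error(metric_counts(confusion_table(0, 0, 5, 0), "ppv"),
               class = "screenval_undefined_error")
  expect_error(confusion_table(-1, 0, 0, 2),
               class = "screenval_validation_error")
})

test_that("Wald interval matches the normal-approximation form", {
  expect_equal(round_half_up(100 * wald_ci(10, 15)), c(42.8, 90.5))
  expect_equal(wald_ci(0, 10), c(0, 0))  # degenerate at the boundary
  # recompute a large-sample bound directly from the formula
  p <- 2903 / 3097
  lower <- p - stats::qnorm(0.975) * sqrt(p * (1 - p) / 3097)
  expect_equal(wald_ci(2903, 3097)[1], lower)
  expect_equal(round_half_up(100 * lower), 92.9)
})

test_that("exact interval has the closed-form boundary bounds", {
  expect_equal(exact_ci(2, 2)[1], 0.025^(1 / 2))
  expect_equal(round_half_up(100 * exact_ci(2, 2)[1]), 15.8)
  expect_equal(round_half_up(100 * exact_ci(7, 7)[1]), 59.0)
  expect_equal(exact_ci(7, 7)[2], 1)
  # mirror symmetry at k = 0
  expect_equal(exact_ci(0, 5), c(0, 1 - 0.025^(1 / 5)))
})

test_that("the auto CI policy uses Wald inside and exact at the boundary", {
  expect_identical(proportion_estimate(10, 15)$method, "wald")
  expect_identical(proportion_estimate(15, 15)$method, "exact")
  expect_identical(proportion_estimate(0, 15)$method, "exact")
  expect_identical(proportion_estimate(0, 0)$method, "degenerate")
  # both intervals contain the point estimate after truncation
  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(1:400, 1)
      k <- sample(0:n, 1)
      for (m in c("wald", "exact")) {
        est <- proportion_estimate(k, n, method = m)
        expect_lte(est$lower, est$point)
        expect_gte(est$upper, est$point)
      }
    }
  })
})

test_that("confusion tables equal an independent per-subject tally in every mode", {
  for (seed in c(11, 12)) {
    rec <- random_records(80, seed)
    for (informant in c("parent", "child", "combined")) {
      for (tau_child in c(1L, 2L)) {
        for (system in c("dsm5", "icd10")) {
          got <- build_confusion(
            rec, informant,
            threshold_policy(tau_parent = 2L, tau_child = tau_child),
            system
          )
          want <- brute_tally(rec, informant, 2, tau_child, system)
          expect_equal(unlist(got[c("tp", "fp", "tn", "fn")]),
                       want, ignore_attr = TRUE)
        }
      }
    }
  }
})

test_that("cells are exhaustive and respect the verification routing", {
  # unscreened cohort: everything lands in tn
  rec <- dplyr::bind_rows(lapply(1:10, function(i) {
    rec_row(paste0("n", i), parent = rep(0, 5))
  }))
  tb <- build_confusion(rec, "parent")
  expect_equal(unlist(tb[c("tp", "fp", "tn", "fn")]), c(0, 0, 10, 0),
               ignore_attr = TRUE)

  # a child-triggered verification can expose a parent-mode false negative
  dyad <- rec_row("d1", parent = rep(0, 5), child = c(1, 1, 0, 0, 0),
                  verified = TRUE, dsm5 = TRUE, icd10 = TRUE)
  tb2 <- build_confusion(dyad, "parent")
  expect_equal(tb2$fn, 1)

  # cell conservation over the records in scope
  rec3 <- random_records(70, 21)
  tb3 <- build_confusion(rec3, "combined")
  expect_equal(tb3$tp + tb3$fp + tb3$tn + tb3$fn,
               sum(rec3$parent_present & rec3$child_present))

  expect_error(build_confusion(rec3[0, ], "parent"),
               class = "screenval_validation_error")
})

test_that("zero-false-negative routing gives fn = 0 in combined mode", {
  cfg <- synthetic_config(n = 2000, prevalence = 0.05, seed = 31)
  rec <- generate_survey(cfg, verification = "routing")
  for (band in c("11-16", "17-19")) {
    tb <- build_confusion(rec[rec$age_band == band, ], "combined",
                          include_singletons = TRUE)
    expect_equal(tb$fn, 0)
  }
})

test_that("accuracy reports agree with metric recomputation and flag undefined cells", {
  tb <- confusion_table(7, 415, 513, 0)
  rep <- accuracy_report(tb)
  for (w in c("se", "sp", "ppv", "npv", "acc")) {
    kn <- metric_counts(tb, w)
    row <- rep[rep$metric == w, ]
    expect_equal(row$point, kn$k / kn$n)
  }
  expect_identical(rep$method[rep$metric == "se"], "exact")
  expect_identical(rep$method[rep$metric == "sp"], "wald")
  expect_equal(round_half_up(100 * rep$point[rep$metric == "sp"]), 55.3)

  none <- accuracy_report(confusion_table(0, 0, 50, 0))
  expect_identical(none$method[none$metric %in% c("ppv", "se")],
                   c("degenerate", "degenerate"))
  expect_equal(none$point[none$metric == "npv"], 1)
  fmt <- format_accuracy(none)
  expect_identical(fmt$display[fmt$metric == "ppv"], "(-)")
})

test_that("pooled t-test matches hand arithmetic and degrees of freedom", {
  same <- compare_metric_sets(c(90, 92, 95), c(90, 92, 95))
  expect_equal(same$t, 0)
  # 3 vs 3 toy, pooled variance by hand: s2 = 2.5, t = -2/sqrt(5/3)
  toy <- compare_metric_sets(c(1, 2, 3), c(2, 4, 6))
  expect_equal(toy$t, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(toy$df, 4)
  # two sets of eight percentages give 14 degrees of freedom
  withr::with_seed(8, {
    res <- compare_metric_sets(stats::runif(8, 50, 100),
                               stats::runif(8, 50, 100))
  })
  expect_equal(res$df, 14)
  expect_error(compare_metric_sets(c(1, 1, 1), c(1, 1, 1)),
               class = "screenval_undefined_error")
})
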