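test_that("generation is reproducible from the seed, byte-for-byte through I/O", {
  cfg <- synthetic_config(n = 80, seed = 424242)
  a <- generate_survey(cfg)
  b <- generate_survey(cfg)
  expect_identical(a, b)
  fa <- withr::local_tempfile()
  fb <- withr::local_tempfile()
  a$disorder <- NULL
  b$disorder <- NULL
  write_records(a, fa)
  write_records(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(identical(a, {
    cc <- generate_survey(synthetic_config(n = 80, seed = 424243))
    cc$disorder <- NULL
    cc
  }))
})

test_that("degenerate prevalences behave as forced", {
  none <- generate_survey(synthetic_config(n = 300, prevalence = 0, seed = 1))
  expect_false(any(none$dx_dsm5, na.rm = TRUE))
  expect_false(any(none$disorder))

  all_cases <- generate_survey(
    synthetic_config(n = 300, prevalence = 1, q_case_parent = 1,
                     q_case_child = 1, seed = 2),
    verification = "complete"
  )
  for (band in c("11-16", "17-19")) {
    sub <- all_cases[all_cases$age_band == band, ]
    tb <- build_confusion(sub, "child",
                          policy = threshold_policy(tau_parent = 1L,
                                                    tau_child = 1L))
    expect_equal(tb$fn, 0) # every item endorsed: sensitivity is 1
    expect_gt(tb$tp, 0)
  }
})

test_that("closed-form screen positivity follows the binomial tail", {
  cfg <- synthetic_config(q_ctrl_parent = 0.1, q_ctrl_child = 0.1)
  cf <- closed_form_metrics(cfg, "child", "11-16",
                            threshold_policy(tau_child = 1L))
  expect_equal(1 - cf$sp, 1 - 0.9^5) # P(score >= 1) = 0.40951
  expect_equal(1 - cf$sp, 0.40951)

  # an uninformative screen: q_case = q_ctrl gives se = 1 - sp exactly
  flat <- synthetic_config(q_case_parent = 0.2, q_case_child = 0.2,
                           q_ctrl_parent = 0.2, q_ctrl_child = 0.2)
  for (mode in c("parent", "child", "combined")) {
    cfm <- closed_form_metrics(flat, mode, "17-19")
    expect_equal(cfm$se, 1 - cfm$sp)
  }

  # heterogeneous per-item probabilities use the Poisson-binomial tail
  het <- synthetic_config(
    q_ctrl_child = list("11-16" = c(0.1, 0.2, 0.3, 0.1, 0.05),
                        "17-19" = 0.1)
  )
  cfh <- closed_form_metrics(het, "child", "11-16",
                             threshold_policy(tau_child = 1L))
  expect_equal(1 - cfh$sp, 1 - prod(1 - c(0.1, 0.2, 0.3, 0.1, 0.05)))
})

test_that("Monte-Carlo metrics from complete verification match the closed form", {
  withr::with_seed(77, {
    for (trial in 1:4) {
      cfg <- synthetic_config(
        n = 20000,
        prevalence = stats::runif(1, 0.05, 0.25),
        p_parent_present = 1, p_child_present = 1,
        q_case_parent = stats::runif(1, 0.3, 0.6),
        q_case_child = stats::runif(1, 0.3, 0.6),
        q_ctrl_parent = stats::runif(1, 0.05, 0.25),
        q_ctrl_child = stats::runif(1, 0.05, 0.25),
        seed = sample.int(1e6, 1)
      )
      rec <- generate_survey(cfg, verification = "complete")
      mode <- c("parent", "child", "combined")[(trial %% 3) + 1]
      tb <- build_confusion(rec[rec$age_band == "11-16", ], mode)
      cf <- closed_form_metrics(cfg, mode, "11-16")
      checks <- list(
        se = c(tb$tp, tb$tp + tb$fn, cf$se),
        sp = c(tb$tn, tb$tn + tb$fp, cf$sp),
        ppv = c(tb$tp, tb$tp + tb$fp, cf$ppv),
        npv = c(tb$tn, tb$tn + tb$fn, cf$npv)
      )
      for (chk in checks) {
        se_hat <- sqrt(chk[3] * (1 - chk[3]) / chk[2])
        expect_lt(abs(chk[1] / chk[2] - chk[3]), 4 * se_hat + 2 / chk[2])
      }
    }
  })
})

test_that("the default configuration sits at the survey's operating point", {
  cfg <- synthetic_config()
  # closed-form marginal screen-positive rates near the published margins
  p_parent <- closed_form_metrics(cfg, "parent", "11-16")$p_screen_positive
  p_child <- closed_form_metrics(cfg, "child", "11-16")$p_screen_positive
  p_self <- closed_form_metrics(cfg, "child", "17-19")$p_screen_positive
  expect_lt(abs(p_parent - 0.065), 0.01)
  expect_lt(abs(p_child - 0.34), 0.03)
  expect_lt(abs(p_self - 0.451), 0.02)
  # and the realised survey tracks the closed form
  rec <- generate_survey(cfg)
  s <- score_records(rec[rec$age_band == "11-16", ])
  expect_lt(abs(mean(s$parent_pos, na.rm = TRUE) - p_parent), 0.015)
  expect_lt(abs(mean(s$child_pos, na.rm = TRUE) - p_child), 0.03)
})

test_that("unsupported informant correlation is rejected, invariants enforced", {
  expect_error(synthetic_config(informant_correlation = 0.3),
               class = "screenval_config_error")
  expect_error(synthetic_config(prevalence = 1.2),
               class = "screenval_config_error")
  rec <- generate_survey(synthetic_config(n = 200, seed = 9))
  expect_silent(validate_records(rec))
  # routing: verified if and only if screen-positive at standard thresholds
  s <- score_records(rec)
  expect_identical(rec$verified, s$screen_pos)
})
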