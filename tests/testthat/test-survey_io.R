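test_that("read -> write -> read is the identity on a well-formed file", {
  cfg <- synthetic_config(n = 60, seed = 101)
  rec <- generate_survey(cfg)
  rec$disorder <- NULL
  expect_gte(nrow(rec), 100)

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, f1)
  back <- read_records(f1)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  write_records(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a custom dialect with renamed columns and missing token round-trips", {
  dia <- survey_dialect(
    columns = c(subject_id = "pid", informant = "who", q1 = "item_a"),
    missing = ".", delim = ";"
  )
  rec <- dplyr::bind_rows(
    rec_row("a", parent = c(1, NA, 0, 0, 0)),
    rec_row("b", child = c(1, 1, 1, 0, 0), verified = TRUE, dsm5 = TRUE,
            icd10 = FALSE)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, f, dia)
  header <- readLines(f, n = 1)
  expect_match(header, "pid;.*who;item_a")
  expect_equal(as.data.frame(read_records(f, dia)), as.data.frame(rec))
})

test_that("routing invariant: screen-negative unverified subjects carry no diagnosis", {
  rec <- rec_row("s1", parent = rep(0, 5), verified = FALSE)
  f <- withr::local_tempfile()
  write_records(rec, f)
  back <- read_records(f)
  expect_true(is.na(back$dx_dsm5) && is.na(back$dx_icd10))
})

test_that("a diagnosis on an unverified subject is rejected, naming the subject", {
  f <- withr::local_tempfile()
  writeLines(c(
    "subject_id,age_band,informant,q1,q2,q3,q4,q5,verified,dx_dsm5,dx_icd10",
    "bad01,11-16,parent,0,0,0,0,0,0,1,NA"
  ), f)
  expect_error(read_records(f), class = "screenval_validation_error",
               regexp = "bad01")
})

test_that("unmapped item values and missing columns are reported precisely", {
  f <- withr::local_tempfile()
  writeLines(c(
    "subject_id,age_band,informant,q1,q2,q3,q4,q5,verified,dx_dsm5,dx_icd10",
    "s1,11-16,parent,yes,no,maybe,0,0,0,NA,NA"
  ), f)
  expect_error(read_records(f), class = "screenval_validation_error",
               regexp = "q3.*line 2")

  f2 <- withr::local_tempfile()
  writeLines(c("subject_id,age_band,informant,q1,q2,q3,q4,q5,verified,dx_dsm5",
               "s1,11-16,parent,0,0,0,0,0,0,NA"), f2)
  expect_error(read_records(f2), class = "screenval_config_error",
               regexp = "dx_icd10")
})

test_that("published metric rows parse losslessly and are bounds-checked", {
  f <- withr::local_tempfile()
  writeLines(c(
    "stratum,n,ppv,ppv_lower,ppv_upper,npv,sensitivity,specificity,accuracy",
    "parents 11-16,3112,4.9,1.9,7.9,99.8,66.7,93.7,93.6"
  ), f)
  tab <- read_published_metrics(f)
  expect_identical(tab$n, 3112)
  expect_identical(
    c(tab$ppv, tab$ppv_lower, tab$ppv_upper, tab$npv, tab$sensitivity,
      tab$specificity, tab$accuracy),
    c(4.9, 1.9, 7.9, 99.8, 66.7, 93.7, 93.6)
  )

  empty <- withr::local_tempfile()
  writeLines("stratum,n,ppv,npv,sensitivity,specificity,accuracy", empty)
  expect_equal(nrow(read_published_metrics(empty)), 0)

  bad <- withr::local_tempfile()
  writeLines(c("stratum,n,ppv,npv,sensitivity,specificity,accuracy",
               "x,100,101.0,99,100,90,90"), bad)
  expect_error(read_published_metrics(bad),
               class = "screenval_validation_error")
})
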