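# builders and independent oracles shared across the suite

# one wide subject row; parent/child are length-5 item vectors or NULL (absent)
rec_row <- function(id, band = "11-16", parent = NULL, child = NULL,
                    verified = FALSE, dsm5 = NA, icd10 = NA) {
  row <- tibble::tibble(
    subject_id = id, age_band = band,
    parent_present = !is.null(parent), child_present = !is.null(child),
    verified = verified, dx_dsm5 = dsm5, dx_icd10 = icd10
  )
  p <- if (is.null(parent)) rep(NA_integer_, 5) else as.integer(parent)
  ch <- if (is.null(child)) rep(NA_integer_, 5) else as.integer(child)
  for (i in 1:5) {
    row[[paste0("parent_q", i)]] <- p[i]
    row[[paste0("child_q", i)]] <- ch[i]
  }
  row[, c("subject_id", "age_band", "parent_present", paste0("parent_q", 1:5),
          "child_present", paste0("child_q", 1:5),
          "verified", "dx_dsm5", "dx_icd10")]
}

# random valid record set: arbitrary items, verification consistent with
# routing at the standard thresholds so records pass validation
random_records <- function(n, seed, band = "11-16") {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      has_p <- stats::runif(1) < 0.8
      has_c <- stats::runif(1) < 0.8
      if (!has_p && !has_c) has_p <- TRUE
      p <- if (has_p) stats::rbinom(5, 1, 0.25) else NULL
      ch <- if (has_c) stats::rbinom(5, 1, 0.25) else NULL
      pos <- (has_p && sum(p) >= 2) || (has_c && sum(ch) >= 1)
      dx <- if (pos) stats::runif(1) < 0.3 else NA
      dx2 <- if (pos) stats::runif(1) < 0.3 else NA
      rec_row(sprintf("R%03d", i), band, p, ch, verified = pos,
              dsm5 = dx, icd10 = dx2)
    })
    dplyr::bind_rows(rows)
  })
}

# independent per-subject loop tally: no shared code with build_confusion
brute_tally <- function(records, informant, tau_parent, tau_child, system,
                        include_singletons = FALSE) {
  cells <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    p_items <- unlist(r[paste0("parent_q", 1:5)])
    c_items <- unlist(r[paste0("child_q", 1:5)])
    p_pos <- if (r$parent_present) sum(p_items == 1, na.rm = TRUE) >= tau_parent else NA
    c_pos <- if (r$child_present) sum(c_items == 1, na.rm = TRUE) >= tau_child else NA
    in_scope <- switch(informant,
      parent = r$parent_present,
      child = r$child_present,
      combined = if (include_singletons) r$parent_present || r$child_present
                 else r$parent_present && r$child_present
    )
    if (!in_scope) next
    idx <- switch(informant,
      parent = p_pos,
      child = c_pos,
      combined = isTRUE(p_pos) || isTRUE(c_pos)
    )
    dx <- r[[paste0("dx_", system)]]
    ref <- isTRUE(dx)
    cell <- if (idx && ref) "tp" else if (idx && !ref) "fp"
            else if (!idx && ref) "fn" else "tn"
    cells[cell] <- cells[cell] + 1
  }
  cells
}

# random confusion table with total at most max_n and at least 1 subject
random_table <- function(max_n = 500) {
  total <- sample(4:max_n, 1)
  cuts <- sort(sample(0:total, 3, replace = TRUE))
  confusion_table(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], total - cuts[3])
}
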