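#' Column dialect for screening-record files
#'
#' Survey extracts name their columns differently; a dialect maps the
#' canonical column names used internally onto the names found in a given
#' file, and declares the token that encodes a skipped item.
#'
#' Canonical columns of the long (one row per informant response) format:
#' `subject_id`, `age_band`, `informant`, `q1`..`q5`, `verified`,
#' `dx_dsm5`, `dx_icd10`. A subject with only one reporting informant has
#' only that informant's row; "informant not asked" is an absent row,
#' which is distinct from an item skipped within a response (the missing
#' token).
#'
#' @param columns named character vector mapping canonical names to source
#'   column names. Defaults to the identity mapping.
#' @param missing token encoding a skipped item / unknown flag (default
#'   `"NA"`).
#' @param delim field delimiter (default `","`).
#' @return a list of class `screenval_dialect`.
#' @export
survey_dialect <- function(columns = NULL, missing = "NA", delim = ",") {
  canonical <- c(
    "subject_id", "age_band", "informant",
    paste0("q", 1:5), "verified", "dx_dsm5", "dx_icd10"
  )
  map <- stats::setNames(canonical, canonical)
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), canonical)
    if (length(bad) > 0) {
      abort_config(paste0(
        "Unknown canonical column(s) in dialect: ",
        paste(bad, collapse = ", ")
      ))
    }
    map[names(columns)] <- unname(columns)
  }
  structure(
    list(columns = map, missing = missing, delim = delim),
    class = "screenval_dialect"
  )
}

#' Read a dialect from a key-value config file
#'
#' The file is YAML with optional keys `missing`, `delim` and a `columns`
#' mapping of canonical to source names.
#'
#' @param path path to the config file.
#' @return a `screenval_dialect`.
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) abort_config(paste0("Config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  survey_dialect(
    columns = if (!is.null(cfg$columns)) unlist(cfg$columns) else NULL,
    missing = cfg$missing %||% "NA",
    delim = cfg$delim %||% ","
  )
}

AGE_BANDS <- c("11-16", "17-19")
INFORMANTS <- c("parent", "child")

# accepted encodings for a binary item; anything else is an error unless it
# equals the dialect's missing token (silent coercion hides data faults)
parse_binary <- function(x, missing_token) {
  low <- tolower(trimws(x))
  out <- rep(NA_integer_, length(x))
  out[low %in% c("1", "yes", "true")] <- 1L
  out[low %in% c("0", "no", "false")] <- 0L
  bad <- !(low %in% c("1", "yes", "true", "0", "no", "false")) &
    !(x %in% missing_token) & !is.na(x)
  attr(out, "bad") <- bad
  out
}

#' Read per-subject screening records
#'
#' Reads a delimited file in the long format (one row per informant
#' response; see [survey_dialect()]) and assembles one record per subject,
#' with optional parent and child responses, the verification flag (was
#' the full diagnostic module administered?) and clinician diagnoses under
#' each classification system.
#'
#' Validation enforced at construction: item values must be one of
#' 1/0, yes/no, true/false or the configured missing token; every subject
#' has at least one response; diagnoses may be present only on verified
#' subjects (screen-negatives were routed past the full module and carry
#' no diagnosis). Malformed rows are reported with their line numbers.
#'
#' @param path path to the delimited file (header row required).
#' @param dialect a [survey_dialect()].
#' @return a tibble with one row per subject: `subject_id`, `age_band`,
#'   `parent_present`, `parent_q1`..`parent_q5`, `child_present`,
#'   `child_q1`..`child_q5`, `verified`, `dx_dsm5`, `dx_icd10`. Item
#'   columns are integer 0/1 with `NA` for a skipped item; item columns of
#'   an absent informant are all `NA`.
#' @export
read_records <- function(path, dialect = survey_dialect()) {
  if (!file.exists(path)) abort_config(paste0("File not found: ", path))
  raw <- readr::read_delim(
    path,
    delim = dialect$delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  miss_cols <- setdiff(unname(dialect$columns), names(raw))
  if (length(miss_cols) > 0) {
    abort_config(paste0(
      "Mandatory column(s) missing from ", path, ": ",
      paste(miss_cols, collapse = ", ")
    ))
  }
  # rename source -> canonical; line numbers count the header as line 1
  inv <- stats::setNames(names(dialect$columns), unname(dialect$columns))
  long <- raw[, unname(dialect$columns)]
  names(long) <- inv[names(long)]
  long$.line <- seq_len(nrow(long)) + 1L

  problems <- character(0)
  note <- function(lines, what) {
    if (length(lines) > 0) {
      problems <<- c(problems, paste0(what, " (line ", lines, ")"))
    }
  }
  note(long$.line[!(long$informant %in% INFORMANTS)],
       "informant not one of parent/child")
  note(long$.line[!(long$age_band %in% AGE_BANDS)],
       "age_band not one of 11-16/17-19")
  for (q in paste0("q", 1:5)) {
    parsed <- parse_binary(long[[q]], dialect$missing)
    note(long$.line[attr(parsed, "bad")], paste0("unrecognised value in ", q))
    long[[q]] <- as.integer(parsed)
  }
  for (fl in c("verified", "dx_dsm5", "dx_icd10")) {
    parsed <- parse_binary(long[[fl]], dialect$missing)
    note(long$.line[attr(parsed, "bad")], paste0("unrecognised value in ", fl))
    long[[fl]] <- as.integer(parsed) == 1L
  }
  note(long$.line[is.na(long$verified)], "verified flag missing")
  dup <- duplicated(long[, c("subject_id", "informant")])
  note(long$.line[dup], "duplicate informant row for subject")
  if (length(problems) > 0) {
    abort_validation(paste0(
      "Malformed rows in ", path, ":\n  ",
      paste(utils::head(problems, 20), collapse = "\n  ")
    ))
  }

  records <- pivot_records(long)
  validate_records(records)
  records
}

# long response rows -> one wide row per subject
pivot_records <- function(long) {
  per_subject <- function(df) {
    row <- tibble::tibble(
      subject_id = df$subject_id[1],
      age_band = df$age_band[1],
      parent_present = "parent" %in% df$informant,
      child_present = "child" %in% df$informant,
      verified = df$verified[1],
      dx_dsm5 = df$dx_dsm5[1],
      dx_icd10 = df$dx_icd10[1]
    )
    for (who in INFORMANTS) {
      sub <- df[df$informant == who, ]
      for (i in 1:5) {
        row[[paste0(if (who == "parent") "parent_q" else "child_q", i)]] <-
          if (nrow(sub) == 1) sub[[paste0("q", i)]][1] else NA_integer_
      }
    }
    if (length(unique(df$age_band)) > 1 ||
        length(unique(df$verified)) > 1 ||
        length(unique(paste(df$dx_dsm5, df$dx_icd10))) > 1) {
      abort_validation(paste0(
        "Inconsistent subject-level fields across informant rows for subject ",
        df$subject_id[1]
      ))
    }
    row
  }
  out <- dplyr::bind_rows(lapply(
    split(long, long$subject_id)[unique(long$subject_id)], per_subject
  ))
  cols <- c(
    "subject_id", "age_band", "parent_present", paste0("parent_q", 1:5),
    "child_present", paste0("child_q", 1:5), "verified", "dx_dsm5", "dx_icd10"
  )
  out[order(out$subject_id), cols]
}

#' Validate a tibble of subject records
#'
#' Asserts the record-model invariants: at least one informant response
#' per subject, item columns 0/1/NA with absent informants all-NA, and no
#' diagnosis on an unverified subject (the routing design administers the
#' full module only to screen-positives, so an unverified subject cannot
#' carry a clinician rating).
#'
#' @param records a tibble as returned by [read_records()] or
#'   [generate_survey()].
#' @return `records`, invisibly, if valid; otherwise an error.
#' @export
validate_records <- function(records) {
  needed <- c(
    "subject_id", "age_band", "parent_present", paste0("parent_q", 1:5),
    "child_present", paste0("child_q", 1:5), "verified", "dx_dsm5", "dx_icd10"
  )
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0) {
    abort_config(paste0("Record table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  }
  none <- !records$parent_present & !records$child_present
  if (any(none)) {
    abort_validation(paste0(
      "Subject(s) with no informant response: ",
      paste(utils::head(records$subject_id[none], 5), collapse = ", ")
    ))
  }
  unverified_dx <- !records$verified &
    (!is.na(records$dx_dsm5) | !is.na(records$dx_icd10))
  if (any(unverified_dx)) {
    abort_validation(paste0(
      "Diagnosis present on unverified subject(s): ",
      paste(utils::head(records$subject_id[unverified_dx], 5), collapse = ", ")
    ))
  }
  for (who in INFORMANTS) {
    qs <- as.matrix(records[paste0(who, "_q", 1:5)])
    present <- records[[paste0(who, "_present")]]
    if (any(!is.na(qs[!present, , drop = FALSE]))) {
      abort_validation(paste0("Items present for absent ", who, " response"))
    }
    if (any(!(qs %in% c(0L, 1L, NA_integer_)))) {
      abort_validation(paste0("Non-binary item value in ", who, " items"))
    }
  }
  invisible(records)
}

#' Write subject records to a delimited file
#'
#' Inverse of [read_records()]: emits the long one-row-per-response
#' format under the given dialect. `read -> write -> read` is the
#' identity on well-formed files.
#'
#' @inheritParams validate_records
#' @param path output path.
#' @param dialect a [survey_dialect()].
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, dialect = survey_dialect()) {
  validate_records(records)
  enc_bin <- function(x) {
    as.character(ifelse(is.na(x), dialect$missing, as.character(as.integer(x))))
  }
  one <- function(who) {
    present <- records[[paste0(who, "_present")]]
    sub <- records[present, ]
    out <- tibble::tibble(
      subject_id = sub$subject_id, age_band = sub$age_band, informant = who
    )
    prefix <- paste0(who, "_q")
    for (i in 1:5) out[[paste0("q", i)]] <- enc_bin(sub[[paste0(prefix, i)]])
    out$verified <- enc_bin(sub$verified)
    out$dx_dsm5 <- enc_bin(sub$dx_dsm5)
    out$dx_icd10 <- enc_bin(sub$dx_icd10)
    out
  }
  long <- dplyr::bind_rows(one("parent"), one("child"))
  long <- long[order(long$subject_id, long$informant), ]
  names(long) <- unname(dialect$columns[names(long)])
  readr::write_delim(long, path, delim = dialect$delim, na = dialect$missing)
  invisible(path)
}

#' Read published accuracy metrics
#'
#' Parses a delimited file of published (rounded) diagnostic-accuracy
#' rows: one row per stratum with `stratum`, `n`, and the five metrics
#' `ppv`, `npv`, `sensitivity`, `specificity`, `accuracy` on the percent
#' scale, each optionally accompanied by printed CI bounds in
#' `<metric>_lower` / `<metric>_upper` columns. Values are percentages
#' rounded to one decimal as printed; parsing preserves them exactly.
#'
#' @param path path to the delimited file.
#' @param delim field delimiter (default `","`).
#' @return a tibble, one row per published stratum; an empty file yields
#'   an empty tibble.
#' @export
read_published_metrics <- function(path, delim = ",") {
  if (!file.exists(path)) abort_config(paste0("File not found: ", path))
  tab <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE
  )
  if (nrow(tab) == 0) return(tab)
  needed <- c("stratum", "n", "ppv", "npv", "sensitivity", "specificity",
              "accuracy")
  miss <- setdiff(needed, names(tab))
  if (length(miss) > 0) {
    abort_config(paste0("Published-metric table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (any(tab$n <= 0 | tab$n != floor(tab$n))) {
    abort_validation("Column n must hold positive integers")
  }
  pct_cols <- setdiff(names(tab), c("stratum", "n", "system"))
  for (cl in pct_cols) {
    v <- tab[[cl]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      abort_validation(paste0("Percentage outside [0, 100] in column ", cl))
    }
  }
  tab
}
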