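.GROUPS  <- c("case", "control", "unknown")
.SEXES   <- c("M", "F")
.TISSUES <- c("blood", "fibroblast")
.COHORTS <- c("discovery", "validation", "classification", "control_pool")

#' Read and validate a sample sheet
#'
#' The sheet is delimited text with columns `sample_id`, `group`, `age`,
#' `sex`, `tissue`, `cohort` (header match is case-insensitive). Categorical
#' columns are validated against closed vocabularies: group in
#' case/control/unknown, sex in M/F, tissue in blood/fibroblast, cohort in
#' discovery/validation/classification/control_pool. Ages are real years and
#' must be non-negative (fractional ages such as 0.33 are legitimate).
#'
#' @param path file path.
#' @param dialect `"tab"` (default) or `"comma"`.
#' @return a `data.frame` with the six validated columns.
#' @export
read_sample_sheet <- function(path, dialect = "tab") {
  df <- .read_table(path, dialect)
  names(df) <- tolower(names(df))
  needed <- c("sample_id", "group", "age", "sex", "tissue", "cohort")
  missing_cols <- setdiff(needed, names(df))
  .stop_if(length(missing_cols) > 0,
           "sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, needed, drop = FALSE]
  if (nrow(df) == 0) return(df)
  df$sample_id <- as.character(df$sample_id)
  .stop_if(anyDuplicated(df$sample_id) > 0, "duplicate sample_id in sample sheet")
  age <- suppressWarnings(as.numeric(df$age))
  .stop_if(anyNA(age), "unparseable age in sample sheet")
  .stop_if(any(age < 0), "negative age in sample sheet")
  df$age <- age
  for (vc in list(c("group", ".GROUPS"), c("sex", ".SEXES"),
                  c("tissue", ".TISSUES"), c("cohort", ".COHORTS"))) {
    col <- vc[1]; vocab <- get(vc[2])
    df[[col]] <- as.character(df[[col]])
    bad <- setdiff(unique(df[[col]]), vocab)
    .stop_if(length(bad) > 0,
             "invalid ", col, " value(s): ", paste(bad, collapse = ", "),
             " (allowed: ", paste(vocab, collapse = ", "), ")")
  }
  df
}

#' Write a sample sheet
#' @param sheet sample-sheet `data.frame`.
#' @inheritParams read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path, dialect = "tab") {
  .write_table(sheet, path, dialect)
}

#' Summarize a cohort's demographics
#'
#' Computes n, sex counts, and the sample mean/SD (n - 1 denominator) and
#' range of age. Values are kept at full precision; round only when
#' presenting (e.g. a mean of 8.375 years prints as 8.4).
#'
#' @param records sample-sheet `data.frame` (at least `sex` and `age`).
#' @return an object of class `cohort_summary`: list with `n`, `n_female`,
#'   `n_male`, `age_mean`, `age_sd`, `age_min`, `age_max`.
#' @export
cohort_summary <- function(records) {
  .stop_if(nrow(records) == 0, "cohort_summary needs at least one record")
  .stop_if(anyNA(records$age), "cohort_summary needs ages for every record")
  out <- list(
    n        = nrow(records),
    n_female = sum(records$sex == "F"),
    n_male   = sum(records$sex == "M"),
    age_mean = mean(records$age),
    age_sd   = if (nrow(records) >= 2) stats::sd(records$age) else NA_real_,
    age_min  = min(records$age),
    age_max  = max(records$age)
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort of %d (%d F / %d M); age %.1f +/- %.1f years (range %g-%g)\n",
              x$n, x$n_female, x$n_male, x$age_mean,
              if (is.na(x$age_sd)) NA_real_ else x$age_sd, x$age_min, x$age_max))
  invisible(x)
}

#' Greedy sex- and age-matched control selection
#'
#' For each case, in input order, selects up to `ratio` unused pool members
#' of the same sex minimizing the absolute age difference; ties are broken
#' by pool order. A case with no same-sex pool member left contributes zero
#' matches (with a warning). `max_age_gap` optionally caps the acceptable
#' age difference; the default (`Inf`) matches purely by nearest age.
#'
#' @param cases,pool sample-sheet `data.frame`s; pool must be disjoint from
#'   cases (by `sample_id`).
#' @param ratio controls per case (positive integer).
#' @param max_age_gap maximum |age difference| in years a match may have.
#' @return the selected pool rows, in order of selection.
#' @export
match_controls <- function(cases, pool, ratio = 1, max_age_gap = Inf) {
  .stop_if(nrow(pool) == 0, "control pool is empty")
  .stop_if(ratio < 1 || ratio != round(ratio), "ratio must be a positive integer")
  .stop_if(length(intersect(cases$sample_id, pool$sample_id)) > 0,
           "pool must be disjoint from cases")
  used <- rep(FALSE, nrow(pool))
  picked <- integer(0)
  for (i in seq_len(nrow(cases))) {
    for (r in seq_len(ratio)) {
      cand <- which(!used & pool$sex == cases$sex[i] &
                      abs(pool$age - cases$age[i]) <= max_age_gap)
      if (length(cand) == 0) {
        if (r == 1)
          warning("no available same-sex match for case ", cases$sample_id[i],
                  call. = FALSE)
        break
      }
      gap <- abs(pool$age[cand] - cases$age[i])
      best <- cand[which.min(gap)]  # which.min keeps the earliest tie
      used[best] <- TRUE
      picked <- c(picked, best)
    }
  }
  pool[picked, , drop = FALSE]
}
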