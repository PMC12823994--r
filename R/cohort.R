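#' Join repertoire metrics with subject covariates into a cohort table
#'
#' Inner join on `subject_id`. Subjects present in the metrics but missing
#' covariates (or vice versa) are excluded with a message giving the count;
#' duplicate subject ids on either side are an error, since each row must
#' represent one subject.
#'
#' @param metrics Tibble of per-subject metrics, as rows of
#'   [compute_metrics()] output (must contain `subject_id`, `S`, `D`).
#' @param covariates Tibble with `subject_id`, `age` (years), `sex`
#'   (`"male"`/`"female"`) and `cmv_status`
#'   (`"positive"`/`"negative"`/`"unknown"`).
#' @return A `tcr_cohort` tibble, one row per subject.
#' @export
build_cohort_table <- function(metrics, covariates) {
  for (nm in c("subject_id", "S", "D")) {
    if (!nm %in% names(metrics)) {
      stop(sprintf("metrics table missing column '%s'", nm), call. = FALSE)
    }
  }
  for (nm in c("subject_id", "age", "sex", "cmv_status")) {
    if (!nm %in% names(covariates)) {
      stop(sprintf("covariates table missing column '%s'", nm), call. = FALSE)
    }
  }
  if (anyDuplicated(metrics$subject_id)) {
    stop("duplicate subject_id in metrics table", call. = FALSE)
  }
  if (anyDuplicated(covariates$subject_id)) {
    stop("duplicate subject_id in covariates table", call. = FALSE)
  }
  validate_covariates(covariates)
  joined <- dplyr::inner_join(metrics, covariates, by = "subject_id")
  n_dropped <- (nrow(metrics) - nrow(joined)) + (nrow(covariates) - nrow(joined))
  if (n_dropped > 0L) {
    message(sprintf("build_cohort_table: excluded %d unmatched subject(s)",
                    n_dropped))
  }
  as_cohort(joined)
}

validate_covariates <- function(covariates) {
  if (any(!is.na(covariates$age) & covariates$age <= 0)) {
    stop("age must be positive", call. = FALSE)
  }
  bad_sex <- setdiff(unique(covariates$sex), c("male", "female", NA))
  if (length(bad_sex) > 0L) {
    stop(sprintf("invalid sex value(s): %s", paste(bad_sex, collapse = ", ")),
         call. = FALSE)
  }
  bad_cmv <- setdiff(unique(covariates$cmv_status),
                     c("positive", "negative", "unknown", NA))
  if (length(bad_cmv) > 0L) {
    stop(sprintf("invalid cmv_status value(s): %s",
                 paste(bad_cmv, collapse = ", ")), call. = FALSE)
  }
  invisible(covariates)
}

as_cohort <- function(x) {
  x <- tibble::as_tibble(x)
  if (!inherits(x, "tcr_cohort")) class(x) <- c("tcr_cohort", class(x))
  x
}

#' Recompute derived metric columns of a cohort table
#'
#' `P_k` columns are defined exactly as `100 * S_k / S`, and `log10_S`,
#' `log10_D` as base-10 logs; these are always recomputed from the stored
#' integer columns so the identities hold after any file round trip.
#'
#' @param cohort A cohort tibble containing `S`, `D` and `S_<k>` columns.
#' @return The cohort with `P_<k>`, `P_1000` etc. and log columns refreshed.
#' @export
add_derived_metrics <- function(cohort) {
  sk_cols <- grep("^S_[0-9]+$", names(cohort), value = TRUE)
  for (sk in sk_cols) {
    kk <- sub("^S_", "", sk)
    cohort[[paste0("P_", kk)]] <- 100 * cohort[[sk]] / cohort$S
  }
  cohort$log10_S <- log10(cohort$S)
  cohort$log10_D <- log10(cohort$D)
  as_cohort(cohort)
}

# column order used on disk; extras are appended after these
.cohort_core_cols <- c("subject_id", "age", "sex", "cmv_status",
                       "S", "D", "S_10", "S_100", "S_1000")

#' Write a cohort table to CSV/TSV
#'
#' The on-disk schema mirrors deposited repertoire-metric tables so real data
#' can be dropped in: `subject_id, age, sex, cmv_status, S, D, S_10, S_100,
#' S_1000`, followed by any extra columns. Derived columns (`P_k`, logs) are
#' not stored; they are recomputed on read from the integer columns.
#'
#' @param cohort A cohort tibble.
#' @param path Output path; a `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  drop <- c(grep("^P_[0-9]+$", names(cohort), value = TRUE),
            "log10_S", "log10_D")
  out <- cohort[, setdiff(names(cohort), drop), drop = FALSE]
  core <- intersect(.cohort_core_cols, names(out))
  out <- out[, c(core, setdiff(names(out), core)), drop = FALSE]
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a cohort table from CSV/TSV
#'
#' Requires at least `subject_id`, `S` and `D`; unknown extra columns are
#' preserved as opaque covariates. Derived `P_k` and log columns are
#' recomputed so that the stored-vs-derived invariants hold exactly.
#'
#' @param path File written by [write_cohort_table()] or any file matching
#'   the documented schema.
#' @return A `tcr_cohort` tibble.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cohort table file not found: '%s'", path), call. = FALSE)
  }
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  x <- reader(path, show_col_types = FALSE, progress = FALSE,
              col_types = readr::cols(subject_id = readr::col_character(),
                                      .default = readr::col_guess()))
  missing_cols <- setdiff(c("subject_id", "S", "D"), names(x))
  if (length(missing_cols) > 0L) {
    stop(sprintf("'%s': missing required cohort column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(x$S) || anyNA(x$D)) {
    stop(sprintf("'%s': rows with missing S or D are not allowed", path),
         call. = FALSE)
  }
  if (anyDuplicated(x$subject_id)) {
    stop(sprintf("'%s': duplicate subject_id", path), call. = FALSE)
  }
  add_derived_metrics(x)
}
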