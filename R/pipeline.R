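#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and writes a covariates CSV, a true-metrics
#' cohort CSV, per-subject clone tables in the simple TSV dialect (when
#' materialised) and a JSON manifest recording the parameters and seed, so a
#' run can be reproduced exactly from its output directory.
#'
#' @param params A [simulation_params()] object.
#' @param out_dir Output directory (created if needed).
#' @param keep_tables Materialise and write per-subject clone tables.
#' @return Invisibly, the [simulate_cohort()] result.
#' @export
run_simulate <- function(params, out_dir, keep_tables = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  sim <- simulate_cohort(params, keep_tables = keep_tables)
  readr::write_csv(sim$covariates, file.path(out_dir, "covariates.csv"),
                   progress = FALSE)
  write_cohort_table(sim$cohort, file.path(out_dir, "cohort_metrics.csv"))
  if (!is.null(sim$clone_tables)) {
    tab_dir <- file.path(out_dir, "clone_tables")
    dir.create(tab_dir, showWarnings = FALSE)
    for (sid in names(sim$clone_tables)) {
      write_clone_table(sim$clone_tables[[sid]],
                        file.path(tab_dir, paste0(sid, ".tsv")))
    }
  }
  manifest <- list(
    stage = "simulate",
    seed = params$seed,
    n_subjects = params$n_subjects,
    n_clamped = sim$n_clamped,
    keep_tables = keep_tables,
    params = unclass(params),
    package_version = as.character(utils::packageVersion("tcrdiv")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sim)
}

#' Compute repertoire metrics for every clone table in a directory
#'
#' Reads each `*.tsv` clone table, computes [compute_metrics()] rows, and
#' collects per-file failures without aborting the run; failures are
#' summarised in a message and returned alongside the metrics.
#'
#' @param input_dir Directory of clone tables in the simple TSV dialect.
#' @param k Top-k cutoffs (default `c(10, 100, 1000)`).
#' @param out Optional path to write the combined metrics table as CSV.
#' @param dialect,clone_col,count_col Passed to [read_clone_table()].
#' @return List with `metrics` (tibble, one row per parsed file) and
#'   `failures` (tibble: `file`, `error`).
#' @export
run_metrics <- function(input_dir, k = c(10L, 100L, 1000L), out = NULL,
                        dialect = "simple", clone_col = "clone_id",
                        count_col = "duplicate_count") {
  files <- list.files(input_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) {
    stop(sprintf("no clone tables (*.tsv) found in '%s'", input_dir),
         call. = FALSE)
  }
  rows <- list(); fails <- list()
  for (f in files) {
    res <- tryCatch(
      compute_metrics(read_clone_table(f, dialect = dialect,
                                       clone_col = clone_col,
                                       count_col = count_col), k = k),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- tibble::tibble(
        file = basename(f), error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  metrics <- dplyr::bind_rows(rows)
  failures <- if (length(fails)) dplyr::bind_rows(fails) else
    tibble::tibble(file = character(0), error = character(0))
  if (nrow(failures) > 0L) {
    message(sprintf("run_metrics: %d of %d file(s) failed to parse",
                    nrow(failures), length(files)))
  }
  if (nrow(metrics) == 0L) {
    stop("no clone table parsed successfully", call. = FALSE)
  }
  if (!is.null(out)) readr::write_csv(metrics, out, progress = FALSE)
  list(metrics = metrics, failures = failures)
}

#' Run the full cohort analysis: curves, models, variance decomposition
#'
#' Orchestrates the descriptive and inferential stages on a cohort table:
#' stratified binned-median curves of `log10_D`, `log10_S` and `P_<k>`
#' against age by sex and by CMV status, the gradient-boosted model with and
#' without the repertoire features, the no-intercept linear model with
#' top-k sensitivity, and (when replicate pairs are supplied) the
#' measurement/intrinsic variance decomposition. All outputs are written
#' under `out_dir` as CSV/JSON together with a manifest; given identical
#' inputs and seed the outputs are bit-identical.
#'
#' @param cohort A cohort tibble (synthetic or a reformatted deposited
#'   metrics table).
#' @param out_dir Output directory.
#' @param replicate_pairs Optional tibble for [estimate_mae()]; the
#'   decomposition stage is skipped with a notice when absent.
#' @param k Headline top-k cutoff (default 1000).
#' @param k_values Cutoffs for [topk_sensitivity()]; defaults to those with
#'   `S_<k>` columns present.
#' @param age_edges Age bin edges for the curves.
#' @param n_boot Bootstrap resamples for curves and coefficient errors.
#' @param folds Cross-validation folds.
#' @param seed Integer seed governing every stochastic stage.
#' @return Invisibly, a list with elements `curves`, `gbm_covariates`,
#'   `gbm_full`, `linear_fit`, `topk`, `decomposition` (or `NULL`).
#' @export
run_analysis <- function(cohort, out_dir, replicate_pairs = NULL,
                         k = 1000L, k_values = NULL,
                         age_edges = seq(20, 80, by = 10),
                         n_boot = 1000L, folds = 5L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- add_derived_metrics(cohort)
  pk <- paste0("P_", k)

  curves <- list()
  for (yv in c("log10_D", "log10_S", pk)) {
    for (strat in c("sex", "cmv_status")) {
      if (!strat %in% names(cohort)) next
      nm <- paste(yv, "by", strat, sep = "_")
      curves[[nm]] <- stratified_curves(cohort, y = yv, stratify_by = strat,
                                        edges = age_edges, n_boot = n_boot,
                                        seed = seed)
    }
  }
  for (nm in names(curves)) {
    readr::write_csv(curves[[nm]],
                     file.path(out_dir, paste0("curve_", nm, ".csv")),
                     progress = FALSE)
  }

  covar_feats <- intersect(c("age", "sex", "cmv_status"), names(cohort))
  gbm_cov <- fit_gbm_cv(cohort, covar_feats, target = "D", folds = folds,
                        seed = seed)
  gbm_full <- fit_gbm_cv(cohort, c(covar_feats, "S", paste0("S_", k)),
                         target = "D", folds = folds, seed = seed)

  fit <- fit_linear_model(cohort, k = k, n_boot = n_boot, folds = folds,
                          seed = seed)
  if (is.null(k_values)) {
    k_values <- sort(as.integer(sub("^S_", "",
                                    grep("^S_[0-9]+$", names(cohort),
                                         value = TRUE))))
  }
  topk <- topk_sensitivity(cohort, k_values = k_values, n_boot = n_boot,
                           folds = folds, seed = seed)

  decomposition <- NULL
  if (!is.null(replicate_pairs)) {
    decomposition <- decompose_variance(fit, replicate_pairs)
  } else {
    message("run_analysis: no replicate pairs supplied; variance decomposition skipped")
  }

  report <- list(
    gbm = list(
      covariates_only = list(r2_cv = gbm_cov$r2_cv,
                             importance = gbm_cov$importance),
      with_repertoire_features = list(r2_cv = gbm_full$r2_cv,
                                      importance = gbm_full$importance)),
    linear_model = list(
      k = fit$k,
      coefficients = as.list(fit$coefficients),
      coefficient_se = as.list(fit$coefficient_se),
      r2_cv = fit$r2_cv, r2_cv_log = fit$r2_cv_log,
      residual_sd_dex = fit$residual_sd_dex,
      residual_sd_raw = fit$residual_sd_raw),
    topk = topk$summary,
    decomposition = if (is.null(decomposition)) NULL else
      unclass(decomposition),
    seed = seed, n_subjects = nrow(cohort),
    package_version = as.character(utils::packageVersion("tcrdiv")))
  jsonlite::write_json(report, file.path(out_dir, "analysis_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_csv(fit$cv_predictions,
                   file.path(out_dir, "predicted_vs_observed.csv"),
                   progress = FALSE)

  invisible(list(curves = curves, gbm_covariates = gbm_cov,
                 gbm_full = gbm_full, linear_fit = fit, topk = topk,
                 decomposition = decomposition))
}
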