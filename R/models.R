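#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about the
#' mean of the observed values. Applicable to held-out predictions, where it
#' can be negative.
#'
#' @param observed,predicted Equal-length numeric vectors; `observed` must
#'   not be constant.
#' @return Scalar R-squared.
#' @export
#' @examples
#' evaluate_r2(c(1, 2, 3), c(1, 2, 4)) # 0.5
evaluate_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  keep <- is.finite(observed) & is.finite(predicted)
  observed <- observed[keep]; predicted <- predicted[keep]
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R^2 is undefined for constant observed values", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

# subject-level folds: seeded random permutation cut into `folds` contiguous
# blocks; every subject lands in exactly one fold
make_folds <- function(n, folds, seed) {
  if (n < folds) {
    stop(sprintf("fewer subjects (%d) than folds (%d)", n, folds),
         call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- diff(round(seq(0, n, length.out = folds + 1L)))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(folds), times = sizes)
  fold
}

# encode model features as a numeric matrix; categorical covariates become
# 0/1 indicators and `groups` maps matrix columns back to feature names
encode_features <- function(cohort, features) {
  cols <- list(); groups <- character(0)
  for (f in features) {
    if (!f %in% names(cohort)) {
      stop(sprintf("unknown feature column '%s'", f), call. = FALSE)
    }
    v <- cohort[[f]]
    if (f == "sex" || (is.character(v) && all(v %in% c("male", "female")))) {
      cols[[paste0(f, "_male")]] <- as.numeric(v == "male")
      groups <- c(groups, f)
    } else if (f == "cmv_status" ||
               (is.character(v) && all(v %in% c("positive", "negative", "unknown")))) {
      cols[[paste0(f, "_positive")]] <- as.numeric(v == "positive")
      groups <- c(groups, f)
      if (any(v == "unknown")) {
        cols[[paste0(f, "_unknown")]] <- as.numeric(v == "unknown")
        groups <- c(groups, f)
      }
    } else if (is.numeric(v)) {
      cols[[f]] <- as.numeric(v)
      groups <- c(groups, f)
    } else {
      stop(sprintf("feature '%s' is neither numeric nor a known categorical",
                   f), call. = FALSE)
    }
  }
  m <- do.call(cbind, cols)
  list(matrix = m, groups = groups)
}

#' Gradient-boosted model of diversity with five-fold cross-validation
#'
#' Fits a gradient-boosted decision-tree regressor (xgboost, squared-error
#' loss, library-default hyperparameters: 100 rounds, `eta = 0.3`,
#' `max_depth = 6`) to a cohort metric. Predictions are produced only on
#' held-out folds over `folds` random splits covering every subject exactly
#' once; feature importances (gain, normalised to sum to 1 over the original
#' feature names, with indicator columns of one categorical collapsed) come
#' from a fit on all the data.
#'
#' @param cohort A cohort tibble.
#' @param features Character vector of feature column names; `sex` and
#'   `cmv_status` are indicator-encoded.
#' @param target Name of the numeric target column (default `"D"`).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param nrounds Boosting rounds (default 100, the library default).
#' @return A `tcr_gbm_fit` list: `cv_predictions` (tibble with
#'   `subject_id`, `observed`, `predicted`, `fold`), `r2_cv`, `importance`
#'   (tibble `feature`, `importance`), `fold_assignments`, `seed`.
#' @export
fit_gbm_cv <- function(cohort, features, target = "D", folds = 5L,
                       seed = 1L, nrounds = 100L) {
  stopifnot(target %in% names(cohort), is.numeric(cohort[[target]]))
  enc <- encode_features(cohort, features)
  X <- enc$matrix
  y <- as.numeric(cohort[[target]])
  n <- nrow(X)
  fold <- make_folds(n, folds, seed)
  params <- list(objective = "reg:squarederror", nthread = 1L)
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    bst <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = nrounds, verbose = 0)
    pred[!tr] <- stats::predict(bst,
                                xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
  }
  dall <- xgboost::xgb.DMatrix(X, label = y)
  full <- xgboost::xgb.train(params = params, data = dall, nrounds = nrounds,
                             verbose = 0)
  imp_raw <- xgboost::xgb.importance(model = full)
  gain <- stats::setNames(rep(0, ncol(X)), colnames(X))
  gain[imp_raw$Feature] <- imp_raw$Gain
  by_feature <- tapply(gain, enc$groups[match(names(gain), colnames(X))], sum)
  by_feature <- by_feature[unique(enc$groups)]
  importance <- tibble::tibble(
    feature = names(by_feature),
    importance = as.numeric(by_feature) / sum(by_feature))
  out <- list(
    cv_predictions = tibble::tibble(
      subject_id = cohort$subject_id, observed = y, predicted = pred,
      fold = fold),
    r2_cv = evaluate_r2(y, pred),
    importance = importance,
    fold_assignments = fold,
    features = features, target = target, nrounds = nrounds, seed = seed)
  class(out) <- "tcr_gbm_fit"
  out
}

#' No-intercept linear model of diversity: D = a*S - b*S_k
#'
#' Least-squares fit of diversity on repertoire size and top-k clone mass,
#' with all variables on their original (non-log) scale and no intercept.
#' The coefficient on `S_k` is stored positive, i.e. the model is
#' `D_hat = a*S - b*S_k`. Coefficients and their 1-sigma standard errors
#' come from a nonparametric pairs bootstrap of a fit to all the data;
#' held-out predictions and the cross-validated R-squared come from
#' `folds`-fold cross-validation.
#'
#' Residual scatter is reported two ways: `residual_sd_dex`, the standard
#' deviation of `log10 D - log10 D_hat` from the full fit (the headline,
#' dex-scale quantity entering the variance decomposition), and
#' `residual_sd_raw` on the original count scale.
#'
#' @param cohort Cohort tibble with columns `S`, `D` and `S_<k>`.
#' @param k Top-k cutoff selecting the `S_<k>` column (default 1000).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed for folds and bootstrap.
#' @param intercept Include an intercept term (default `FALSE`, matching the
#'   model definition).
#' @return A `tcr_fit_result` list: `coefficients` (`a`, `b`),
#'   `coefficient_se`, `coefficient_ci` (95% percentile bootstrap),
#'   `cv_predictions`, `r2_cv`, `r2_cv_log`, `residual_sd_dex`,
#'   `residual_sd_raw`, `fold_assignments`, `k`, `seed`, `n`.
#' @export
fit_linear_model <- function(cohort, k = 1000L, n_boot = 1000L, folds = 5L,
                             seed = 1L, intercept = FALSE) {
  sk_col <- paste0("S_", k)
  for (nm in c("S", "D", sk_col)) {
    if (!nm %in% names(cohort)) {
      stop(sprintf("cohort is missing column '%s'", nm), call. = FALSE)
    }
  }
  n <- nrow(cohort)
  if (n < 10L) stop("need at least 10 subjects", call. = FALSE)
  S <- as.numeric(cohort$S)
  Sk <- as.numeric(cohort[[sk_col]])
  D <- as.numeric(cohort$D)
  if (stats::sd(Sk) == 0) {
    stop(sprintf("degenerate design: column '%s' is constant", sk_col),
         call. = FALSE)
  }
  if (abs(stats::cor(S, Sk)) > 1 - 1e-10) {
    stop(sprintf("collinear design: '%s' is proportional to S", sk_col),
         call. = FALSE)
  }
  X <- if (intercept) cbind(`(Intercept)` = 1, S = S, S_k = Sk)
       else cbind(S = S, S_k = Sk)
  ols <- function(rows) {
    fit <- stats::lm.fit(X[rows, , drop = FALSE], D[rows])
    fit$coefficients
  }
  coef_full <- ols(seq_len(n))
  # pairs bootstrap of the full-data fit
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) ols(sample.int(n, n, replace = TRUE)),
           numeric(ncol(X)))
  })
  se <- apply(boot, 1L, stats::sd)
  ci <- apply(boot, 1L, stats::quantile, probs = c(0.025, 0.975))
  # sign convention: model is D_hat = a*S - b*S_k with b stored positive
  flip <- function(v) { v["S_k"] <- -v["S_k"]; names(v)[names(v) == "S"] <- "a"
    names(v)[names(v) == "S_k"] <- "b"; v }
  coefficients <- flip(coef_full)
  coefficient_se <- stats::setNames(se, names(coefficients))
  ci_out <- ci
  colnames(ci_out) <- names(coefficients)
  b_idx <- which(colnames(ci_out) == "b")
  ci_out[, b_idx] <- -rev(ci_out[, b_idx])

  fold <- make_folds(n, folds, seed)
  pred_cv <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    cf <- ols(which(tr))
    pred_cv[!tr] <- X[!tr, , drop = FALSE] %*% cf
  }
  pred_full <- as.numeric(X %*% coef_full)
  pos <- pred_full > 0 & D > 0
  resid_dex <- log10(D[pos]) - log10(pred_full[pos])
  pos_cv <- pred_cv > 0 & D > 0
  out <- list(
    coefficients = coefficients,
    coefficient_se = coefficient_se,
    coefficient_ci = ci_out,
    cv_predictions = tibble::tibble(
      subject_id = cohort$subject_id, observed = D, predicted = pred_cv,
      fold = fold),
    r2_cv = evaluate_r2(D, pred_cv),
    r2_cv_log = evaluate_r2(log10(D[pos_cv]), log10(pred_cv[pos_cv])),
    residual_sd_dex = stats::sd(resid_dex),
    residual_sd_raw = stats::sd(D - pred_full),
    fold_assignments = fold, k = k, seed = seed, n = n,
    intercept = intercept, n_boot = n_boot)
  class(out) <- "tcr_fit_result"
  out
}

#' @export
print.tcr_fit_result <- function(x, ...) {
  a <- x$coefficients["a"]; b <- x$coefficients["b"]
  cat(sprintf("Linear diversity model (k = %d, n = %d)\n", x$k, x$n))
  cat(sprintf("  D_hat = (%.3f +/- %.3f) * S - (%.3f +/- %.3f) * S_%d\n",
              a, x$coefficient_se["a"], b, x$coefficient_se["b"], x$k))
  cat(sprintf("  CV R^2 (raw) = %.3f, CV R^2 (log10) = %.3f\n",
              x$r2_cv, x$r2_cv_log))
  cat(sprintf("  residual sd = %.4f dex (%.0f raw)\n",
              x$residual_sd_dex, x$residual_sd_raw))
  invisible(x)
}

#' Sensitivity of the linear diversity model to the top-k cutoff
#'
#' Re-fits [fit_linear_model()] for each requested cutoff `k` (the cohort
#' must carry the matching `S_<k>` columns) and tabulates coefficients and
#' cross-validated R-squared for comparison across cutoffs.
#'
#' @param cohort Cohort tibble with the `S_<k>` columns.
#' @param k_values Cutoffs to fit (default `c(10, 100, 1000)`).
#' @inheritParams fit_linear_model
#' @return List with `fits` (named list of `tcr_fit_result`) and `summary`
#'   (tibble: `k`, `a`, `b`, `se_a`, `se_b`, `r2_cv`, `r2_cv_log`,
#'   `residual_sd_dex`).
#' @export
topk_sensitivity <- function(cohort, k_values = c(10L, 100L, 1000L),
                             n_boot = 1000L, folds = 5L, seed = 1L) {
  fits <- lapply(k_values, function(kk) {
    fit_linear_model(cohort, k = kk, n_boot = n_boot, folds = folds,
                     seed = seed)
  })
  names(fits) <- paste0("k", k_values)
  summary <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(k = f$k, a = f$coefficients["a"], b = f$coefficients["b"],
                   se_a = f$coefficient_se["a"], se_b = f$coefficient_se["b"],
                   r2_cv = f$r2_cv, r2_cv_log = f$r2_cv_log,
                   residual_sd_dex = f$residual_sd_dex)
  }))
  list(fits = fits, summary = summary)
}
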