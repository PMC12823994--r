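#' Minimum achievable error (MAE) from paired replicate measurements
#'
#' Measurement errors in repertoire size and diversity are correlated, so the
#' measurement floor is estimated from the ratio `D/S`: for each subject
#' measured twice, take the difference in `log10(D/S)` between the two
#' measurements, and return the sample standard deviation (denominator
#' `n - 1`) of those differences, in dex. This difference-scale quantity is
#' the `sigma_m` entering [intrinsic_scatter()]; the per-measurement noise is
#' smaller by a factor `sqrt(2)` and is available via `per_measurement`.
#'
#' @param pairs Tibble of paired measurements with columns `S_1`, `D_1`,
#'   `S_2`, `D_2` (as produced by [simulate_replicates()]).
#' @param per_measurement If `TRUE`, divide by `sqrt(2)` to report the
#'   implied per-measurement standard deviation instead (default `FALSE`).
#' @return Scalar standard deviation in dex.
#' @export
estimate_mae <- function(pairs, per_measurement = FALSE) {
  need <- c("S_1", "D_1", "S_2", "D_2")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0L) {
    stop(sprintf("replicate pairs missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(pairs) < 2L) {
    stop("need at least 2 replicate pairs to estimate a standard deviation",
         call. = FALSE)
  }
  vals <- unlist(pairs[need], use.names = FALSE)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all D and S measurements must be positive and finite",
         call. = FALSE)
  }
  diffs <- (log10(pairs$D_1 / pairs$S_1)) - (log10(pairs$D_2 / pairs$S_2))
  out <- stats::sd(diffs)
  if (per_measurement) out / sqrt(2) else out
}

#' Intrinsic scatter by quadrature subtraction of measurement error
#'
#' `sigma_i = sqrt(sigma_r^2 - sigma_m^2)`: the residual biological scatter
#' left after subtracting the measurement floor from a model's residual
#' scatter in quadrature. A measurement floor exceeding the model residual
#' is an error (it signals the model residual is below what the measurements
#' can resolve), never a silent zero.
#'
#' @param sigma_r Model residual scatter (dex), `>= 0`.
#' @param sigma_m Measurement uncertainty / MAE (dex), `>= 0`.
#' @return `sigma_i` in dex.
#' @export
#' @examples
#' intrinsic_scatter(0.031, 0.027) # ~0.015 dex
#' intrinsic_scatter(0.05, 0.03)   # 0.04
intrinsic_scatter <- function(sigma_r, sigma_m) {
  stopifnot(is.finite(sigma_r), is.finite(sigma_m),
            sigma_r >= 0, sigma_m >= 0)
  if (sigma_m > sigma_r) {
    stop(sprintf(
      "measurement error (%.4g dex) exceeds model residual scatter (%.4g dex): quadrature subtraction is undefined",
      sigma_m, sigma_r), call. = FALSE)
  }
  sqrt(sigma_r^2 - sigma_m^2)
}

#' Decompose model residual scatter into measurement and intrinsic parts
#'
#' Combines a fitted diversity model and paired replicate measurements:
#' `sigma_r` is the model's dex-scale residual standard deviation, `sigma_m`
#' the MAE from [estimate_mae()], and `sigma_i` their quadrature difference.
#' The unexplained fraction of diversity variation is reported two ways,
#' since either reading is defensible: `fraction_unexplained_r2 = 1 - R^2`
#' of the cross-validated predictions, and
#' `fraction_unexplained_variance = (sigma_i / sigma_total)^2`, where
#' `sigma_total` is the cohort standard deviation of `log10 D` after the
#' same quadrature correction for measurement noise.
#'
#' @param fit A `tcr_fit_result` from [fit_linear_model()] (any object with
#'   `residual_sd_dex`, `r2_cv` and `cv_predictions` works).
#' @param pairs Replicate pairs for [estimate_mae()].
#' @return A `tcr_variance_decomposition` list: `sigma_r`, `sigma_m`,
#'   `sigma_i`, `sigma_total`, `fraction_unexplained_r2`,
#'   `fraction_unexplained_variance`.
#' @export
decompose_variance <- function(fit, pairs) {
  if (is.null(fit$residual_sd_dex)) {
    stop("fit does not carry a dex-scale residual sd", call. = FALSE)
  }
  sigma_r <- fit$residual_sd_dex
  sigma_m <- estimate_mae(pairs)
  sigma_i <- intrinsic_scatter(sigma_r, sigma_m)
  obs <- fit$cv_predictions$observed
  sd_logD <- stats::sd(log10(obs[obs > 0]))
  sigma_total <- if (sd_logD > sigma_m) {
    sqrt(sd_logD^2 - sigma_m^2)
  } else {
    NA_real_
  }
  out <- list(
    sigma_r = sigma_r, sigma_m = sigma_m, sigma_i = sigma_i,
    sigma_total = sigma_total,
    fraction_unexplained_r2 = 1 - fit$r2_cv,
    fraction_unexplained_variance =
      if (is.na(sigma_total)) NA_real_ else (sigma_i / sigma_total)^2)
  class(out) <- "tcr_variance_decomposition"
  out
}

#' @export
print.tcr_variance_decomposition <- function(x, ...) {
  # display rounds to 2 significant figures; stored values keep full precision
  cat("Variance decomposition of diversity residual scatter (dex)\n")
  cat(sprintf("  sigma_r (model residual)      = %s\n", signif(x$sigma_r, 2)))
  cat(sprintf("  sigma_m (measurement, MAE)    = %s\n", signif(x$sigma_m, 2)))
  cat(sprintf("  sigma_i (intrinsic, quadrature) = %s\n", signif(x$sigma_i, 2)))
  cat(sprintf("  unexplained: 1 - CV R^2 = %s; (sigma_i/sigma_total)^2 = %s\n",
              signif(x$fraction_unexplained_r2, 2),
              signif(x$fraction_unexplained_variance, 2)))
  invisible(x)
}
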