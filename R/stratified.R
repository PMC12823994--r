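#' Binned medians with percentile-bootstrap confidence intervals
#'
#' Computes the median of `y` within bins of `x`, with a percentile bootstrap
#' confidence interval from resampling within each bin. Bins whose occupancy
#' falls below `min_n` are flagged rather than silently dropped; empty bins
#' yield `NA` medians and are flagged.
#'
#' @param x,y Paired numeric vectors.
#' @param edges Strictly increasing bin edges (left-closed, right-open;
#'   the last bin is closed on both sides).
#' @param n_boot Bootstrap resamples per bin (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @param min_n Minimum occupancy before a bin is considered reliable
#'   (default 20; below it the row is flagged).
#' @param stratum Label stored in the `stratum` column.
#' @return A `tcr_binned_curve` tibble: `bin_low`, `bin_high`, `bin_mid`,
#'   `n`, `median`, `ci_low`, `ci_high`, quantile bands `q05`, `q25`, `q75`,
#'   `q95` (central 50% and 90% of the data per bin), `flagged`, `stratum`.
#' @export
binned_median_curve <- function(x, y, edges, n_boot = 1000L, seed = NULL,
                                conf = 0.95, min_n = 20L, stratum = "all") {
  stopifnot(length(x) == length(y), length(edges) >= 2L,
            all(diff(edges) > 0), n_boot >= 1L)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  nb <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  alpha <- (1 - conf) / 2
  run <- function() {
    rows <- vector("list", nb)
    for (b in seq_len(nb)) {
      yb <- y[idx == b]
      n <- length(yb)
      if (n == 0L) {
        med <- NA_real_
        ci <- c(NA_real_, NA_real_)
        qs <- rep(NA_real_, 4L)
      } else {
        med <- stats::median(yb)
        boot_meds <- vapply(seq_len(n_boot), function(i) {
          stats::median(yb[sample.int(n, n, replace = TRUE)])
        }, numeric(1))
        ci <- stats::quantile(boot_meds, c(alpha, 1 - alpha), names = FALSE)
        qs <- stats::quantile(yb, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
      }
      rows[[b]] <- tibble::tibble(
        bin_low = edges[b], bin_high = edges[b + 1L],
        bin_mid = (edges[b] + edges[b + 1L]) / 2,
        n = n, median = med, ci_low = ci[1L], ci_high = ci[2L],
        q05 = if (n) qs[1L] else NA_real_, q25 = if (n) qs[2L] else NA_real_,
        q75 = if (n) qs[3L] else NA_real_, q95 = if (n) qs[4L] else NA_real_,
        flagged = n < min_n, stratum = stratum)
    }
    dplyr::bind_rows(rows)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("tcr_binned_curve", class(out))
  out
}

#' Stratified binned-median curves for a cohort metric
#'
#' One [binned_median_curve()] per level of a stratifying covariate, on
#' shared bin edges, with central-50% and central-90% quantile bands per bin
#' (the shading used in the descriptive cohort figures). Default edges are
#' decade-wide age bins from 20 to 80.
#'
#' @param cohort A cohort tibble.
#' @param y Name of the metric column (e.g. `"log10_D"`).
#' @param x Name of the numeric covariate on the horizontal axis
#'   (default `"age"`).
#' @param stratify_by Name of the categorical column to stratify on
#'   (e.g. `"sex"`, `"cmv_status"`), or `NULL` for a single curve.
#' @inheritParams binned_median_curve
#' @return A `tcr_binned_curve` tibble with one block of rows per stratum.
#' @export
stratified_curves <- function(cohort, y, stratify_by = NULL, x = "age",
                              edges = seq(20, 80, by = 10), n_boot = 1000L,
                              seed = NULL, min_n = 20L) {
  for (nm in c(y, x, stratify_by)) {
    if (!nm %in% names(cohort)) {
      stop(sprintf("unknown cohort column '%s'", nm), call. = FALSE)
    }
  }
  if (is.null(stratify_by)) {
    return(binned_median_curve(cohort[[x]], cohort[[y]], edges,
                               n_boot = n_boot, seed = seed, min_n = min_n))
  }
  levels <- sort(unique(cohort[[stratify_by]]))
  if (length(levels) < 2L) {
    warning(sprintf("stratifying column '%s' has a single level; returning one curve",
                    stratify_by), call. = FALSE)
  }
  curves <- lapply(seq_along(levels), function(i) {
    sel <- cohort[[stratify_by]] == levels[i]
    binned_median_curve(cohort[[x]][sel], cohort[[y]][sel], edges,
                        n_boot = n_boot,
                        seed = if (is.null(seed)) NULL else seed + i,
                        min_n = min_n, stratum = as.character(levels[i]))
  })
  out <- dplyr::bind_rows(curves)
  class(out) <- c("tcr_binned_curve", class(out))
  out
}

#' Conditional median grid: median y vs x within bins of a third metric
#'
#' Computes binned-median curves of `y` against `x` separately within bins of
#' a conditioning metric (e.g. median `log10_D` vs age in bins of `log10_S`
#' or of `P_1000`), optionally further stratified by a categorical covariate.
#' Grid cells with no data are flagged.
#'
#' @param cohort A cohort tibble.
#' @param y,x Metric / covariate column names.
#' @param condition_on Name of the conditioning metric column.
#' @param condition_edges Bin edges for the conditioning metric.
#' @param x_edges Bin edges for `x`.
#' @param stratify_by Optional categorical column name.
#' @inheritParams binned_median_curve
#' @return A `tcr_binned_curve` tibble with a `condition_bin` label column.
#' @export
conditional_median_grid <- function(cohort, y, x, condition_on,
                                    condition_edges, x_edges,
                                    stratify_by = NULL, n_boot = 200L,
                                    seed = NULL, min_n = 20L) {
  for (nm in c(y, x, condition_on, stratify_by)) {
    if (!nm %in% names(cohort)) {
      stop(sprintf("unknown cohort column '%s'", nm), call. = FALSE)
    }
  }
  cbin <- findInterval(cohort[[condition_on]], condition_edges,
                       rightmost.closed = TRUE)
  blocks <- list()
  for (b in seq_len(length(condition_edges) - 1L)) {
    sub <- cohort[cbin == b, , drop = FALSE]
    lab <- sprintf("%s in [%g, %g)", condition_on,
                   condition_edges[b], condition_edges[b + 1L])
    cur <- stratified_curves(sub, y = y, stratify_by = stratify_by, x = x,
                             edges = x_edges, n_boot = n_boot,
                             seed = if (is.null(seed)) NULL else seed + 100L * b,
                             min_n = min_n)
    cur$condition_bin <- lab
    blocks[[b]] <- cur
  }
  out <- dplyr::bind_rows(blocks)
  class(out) <- c("tcr_binned_curve", class(out))
  out
}

#' Spearman rank correlation with mid-rank tie handling
#'
#' Rank correlation computed from mid-ranks, with a two-sided p-value from
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom (computed on the log scale, so extremely small
#' p-values at large cohort sizes do not underflow to zero unnecessarily).
#'
#' @param x,y Paired numeric vectors, `n >= 3`, neither constant.
#' @return List with `rho`, `p_value` and `n`.
#' @export
#' @examples
#' spearman_correlation(1:5, c(1, 3, 2, 5, 4)) # rho = 0.8
spearman_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite observations", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("rank correlation is undefined for a constant input vector",
         call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y) # mid-ranks for ties
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * exp(stats::pt(-abs(tval), df = n - 2, log.p = TRUE))
  }
  list(rho = rho, p_value = min(p, 1), n = n)
}
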