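test_that("binned medians behave on degenerate and tiny inputs", {
  x <- runif(200, 0, 10)
  cst <- binned_median_curve(x, rep(3.5, 200), edges = c(0, 5, 10),
                             n_boot = 100, seed = 1)
  expect_equal(cst$median, c(3.5, 3.5))
  expect_equal(cst$ci_low, cst$ci_high) # constant data: zero-width CI

  one <- binned_median_curve(c(1, 2, 3), c(1, 2, 3), edges = c(0, 4),
                             n_boot = 50, seed = 1, min_n = 1)
  expect_equal(one$median, 2)

  # empty bin: NA median, flagged rather than dropped
  sparse <- binned_median_curve(c(1, 1.5), c(5, 6), edges = c(0, 2, 4),
                                n_boot = 50, seed = 1)
  expect_equal(nrow(sparse), 2)
  expect_true(is.na(sparse$median[2]))
  expect_true(all(sparse$flagged))
})

test_that("bootstrap CIs contain the median and shrink with sample size", {
  withr::local_seed(55)
  x <- runif(20000)
  y <- rnorm(20000, mean = 2)
  cur <- binned_median_curve(x, y, edges = c(0, 1), n_boot = 300, seed = 9)
  expect_true(cur$ci_low <= cur$median && cur$median <= cur$ci_high)
  small <- binned_median_curve(x[1:500], y[1:500], edges = c(0, 1),
                               n_boot = 300, seed = 9)
  width_big <- cur$ci_high - cur$ci_low
  width_small <- small$ci_high - small$ci_low
  # 1/sqrt(n) scaling: 40x the data, ~6.3x narrower; allow a loose band
  expect_lt(width_big, width_small / 3)
})

test_that("bootstrap CIs achieve near-nominal coverage for a known median", {
  withr::local_seed(202)
  hits <- 0L
  reps <- 60L
  for (i in seq_len(reps)) {
    y <- rlnorm(400, meanlog = 1, sdlog = 0.6) # known median exp(1)
    cur <- binned_median_curve(runif(400), y, edges = c(0, 1),
                               n_boot = 200)
    hits <- hits + (cur$ci_low <= exp(1) && exp(1) <= cur$ci_high)
  }
  expect_gte(hits / reps, 0.85) # nominal 95%, binomial noise at 60 reps
})

test_that("stratified curves separate strata with a configured offset", {
  p <- simulation_params(
    n_subjects = 4000, seed = 21,
    d_model = list(kind = "lognormal"),
    d_lognormal = list(median_log10 = log10(319802), sd = 0.08,
                       corr_with_s = 0, age_slope = -0.005,
                       male_offset = -0.05, cmv_offset = 0))
  co <- simulate_cohort(p)$cohort
  cur <- stratified_curves(co, y = "log10_D", stratify_by = "sex",
                           n_boot = 100, seed = 3)
  wide <- sex_curves_wide(cur)
  occupied <- wide$n_male >= 100 & wide$n_female >= 100
  expect_true(all(wide$median_male[occupied] < wide$median_female[occupied]))

  # identical data in both strata: identical medians
  yrep <- rnorm(120)
  co2 <- tibble::tibble(
    age = rep(rep(seq(25, 75, by = 10), each = 20), times = 2),
    log10_D = rep(yrep, times = 2),
    sex = rep(c("male", "female"), each = 120))
  cur2 <- stratified_curves(co2, y = "log10_D", stratify_by = "sex",
                            n_boot = 50, seed = 3)
  m <- split(cur2$median, cur2$stratum)
  expect_equal(m$male, m$female)

  # constant stratifying column: single curve plus a warning
  co3 <- co
  co3$sex <- "female"
  expect_warning(cur3 <- stratified_curves(co3, y = "log10_D",
                                           stratify_by = "sex",
                                           n_boot = 50, seed = 3),
                 "single level")
  expect_equal(unique(cur3$stratum), "female")

  expect_error(stratified_curves(co, y = "nope", stratify_by = "sex"),
               "unknown cohort column")
})

test_that("conditional median grids order curves by the conditioning metric", {
  # deterministic relation D = 0.8*S - 1.0*S_1000: at fixed S, D falls as
  # P_1000 rises
  co <- exact_cohort(n = 3000, seed = 12)
  grid <- conditional_median_grid(
    co, y = "D", x = "log10_S", condition_on = "P_1000",
    condition_edges = c(0, 15, 25, 100),
    x_edges = quantile(co$log10_S, c(0, .25, .5, .75, 1), names = FALSE),
    n_boot = 50, seed = 7, min_n = 10)
  for (bin in unique(grid$bin_low)) {
    rows <- grid[grid$bin_low == bin & !grid$flagged, ]
    if (nrow(rows) >= 2) {
      expect_true(all(diff(rows$median) < 0))
    }
  }
  # y a function of the condition alone: curves flat in x
  co$flat <- round(co$P_1000)
  g2 <- conditional_median_grid(
    co, y = "flat", x = "age", condition_on = "P_1000",
    condition_edges = c(9.9, 10.1), x_edges = c(20, 50, 80),
    n_boot = 20, seed = 7, min_n = 1)
  g2 <- g2[!is.na(g2$median), ]
  expect_equal(length(unique(g2$median)), 1)
})

test_that("spearman correlation uses mid-ranks and matches an oracle", {
  expect_equal(spearman_correlation(1:20, exp(1:20))$rho, 1)
  expect_equal(spearman_correlation(1:20, -(1:20))$rho, -1)
  # hand value: d^2 = (0,1,1,1,1), rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_correlation(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)

  # oracle: cor.test with tied data (mid-ranks)
  withr::local_seed(66)
  x <- sample(1:10, 200, replace = TRUE)
  y <- x + sample(1:10, 200, replace = TRUE)
  ours <- spearman_correlation(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)

  # invariance under strictly monotone transforms
  a <- rnorm(100); b <- rnorm(100)
  r0 <- spearman_correlation(a, b)$rho
  expect_equal(spearman_correlation(exp(a), b)$rho, r0)
  expect_equal(spearman_correlation(a, qlogis(plogis(b)))$rho, r0)

  expect_error(spearman_correlation(rep(1, 10), 1:10), "constant")
  expect_error(spearman_correlation(1:2, 2:3), "at least 3")
})
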