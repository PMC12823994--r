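test_that("constructive generator hits exact metric targets", {
  # small worked case: top block {4,4}, tail {2}
  counts <- construct_counts(10, 3, 8, 2)
  expect_equal(sort(counts, decreasing = TRUE), c(4, 4, 2))
  expect_roundtrip(10, 3, 8, 2)

  # repertoire-scale target
  expect_roundtrip(2e6, 3e5, 2e5, 1000)

  # geometric top-block profile round-trips too, with a decaying top block
  cts <- construct_counts(2e5, 5e4, 6e4, 1000, profile = "geometric",
                          decay = 0.99)
  expect_roundtrip(2e5, 5e4, 6e4, 1000, profile = "geometric")
  top <- sort(cts, decreasing = TRUE)[1:1000]
  expect_true(top[1] > top[1000])

  # infeasible targets are rejected with the violated constraint named
  expect_error(construct_counts(7, 8, 7, 2), "D > S")
  expect_error(construct_counts(10, 5, 2, 3), "S_k < k")
  expect_error(construct_counts(10, 5, 9, 3), "tail clone")
  expect_error(construct_counts(10, 4, 4, 2), "rank inversion")
  expect_error(construct_counts(10, 2, 7, 5), "S_k must equal S")
})

test_that("round trip holds on an exhaustive small grid and random large triples", {
  for (S in 1:25) for (D in 1:S) for (k in 1:D) {
    lo <- if (D <= k) S else k
    hi <- if (D <= k) S else S - (D - k)
    for (sk in lo:hi) {
      if (isTRUE(triple_feasibility(S, D, sk, k))) {
        m <- compute_metrics(construct_counts(S, D, sk, k), k = k)
        if (m$S != S || m$D != D || m[[paste0("S_", k)]] != sk) {
          fail(sprintf("round trip broken at (S=%d, D=%d, S_k=%d, k=%d)",
                       S, D, sk, k))
        }
      }
    }
  }
  succeed()
  withr::local_seed(77)
  for (i in 1:50) {
    tr <- random_large_triple()
    expect_roundtrip(tr$S, tr$D, tr$S_k, tr$k)
  }
})

test_that("feasibility clamping projects onto the feasible set", {
  withr::local_seed(42)
  for (i in 1:200) {
    S <- sample(1:5000, 1)
    D <- sample(1:6000, 1)
    k <- sample(c(2L, 10L, 50L), 1)
    S_k <- sample(0:S, 1)
    cl <- clamp_triple(S, D, S_k, k)
    expect_true(isTRUE(triple_feasibility(cl$S, cl$D, cl$S_k, k)))
  }
  # an already-feasible triple is untouched
  cl <- clamp_triple(10, 3, 8, 2)
  expect_false(cl$clamped)
  expect_equal(cl$S_k, 8)
})

test_that("cohort simulation is reproducible and degenerates correctly", {
  p <- simulation_params(n_subjects = 40, seed = 123)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$cohort, b$cohort)

  # all effects and noise zero: every subject identical at the baselines
  p0 <- simulation_params(
    n_subjects = 15, seed = 5,
    s_model = list(median_log10 = log10(518618), sd = 0, age_slope = 0,
                   male_offset = 0, cmv_offset = 0),
    p1000_model = list(value_at_20 = 10, age_slope = 0, male_offset = 0,
                       cmv_offset = 0, noise_sd = 0),
    d_model = list(kind = "linear", a = 0.825, b = 0.965, noise_sd_dex = 0))
  co <- simulate_cohort(p0)$cohort
  expect_equal(unique(co$S), 518618)
  expect_equal(unique(co$S_1000), round(0.10 * 518618))
  expect_equal(unique(co$D),
               round(0.825 * 518618 - 0.965 * round(0.10 * 518618)))

  # inconsistent settings (diversity target far above repertoire size) abort
  p_bad <- simulation_params(
    n_subjects = 30, seed = 5,
    d_model = list(kind = "lognormal"),
    d_lognormal = list(median_log10 = 7.5, sd = 0.01, corr_with_s = 0,
                       age_slope = 0, male_offset = 0, cmv_offset = 0))
  expect_error(simulate_cohort(p_bad), "inconsistent simulation parameters")
})

test_that("generated cohorts carry the configured covariate structure", {
  # decade-binned medians of log10_D recover the configured age slope
  p <- simulation_params(
    n_subjects = 4000, seed = 31,
    d_model = list(kind = "lognormal"),
    d_lognormal = list(median_log10 = log10(319802), sd = 0.05,
                       corr_with_s = 0, age_slope = -0.005,
                       male_offset = 0, cmv_offset = 0))
  co <- simulate_cohort(p)$cohort
  fit <- stats::lm(log10_D ~ age, data = co)
  slope <- stats::coef(fit)["age"]
  se <- summary(fit)$coefficients["age", "Std. Error"]
  expect_lt(abs(slope - (-0.005)), 3 * se)
})

test_that("subsampling models finite sequencing depth", {
  ct <- clone_table(paste0("c", 1:4), c(10, 5, 3, 2))

  # exhaustive draw without replacement returns the table unchanged
  full <- subsample_repertoire(ct, depth = 20, seed = 1, replace = FALSE)
  expect_equal(full$templates[match(ct$clone_id, full$clone_id)],
               ct$templates)
  expect_error(subsample_repertoire(ct, depth = 21, replace = FALSE),
               "exceeds total")

  # a single template yields a single clone
  one <- subsample_repertoire(ct, depth = 1, seed = 2)
  expect_equal(sum(one$templates), 1)
  expect_equal(nrow(one), 1)

  # with replacement: total is the depth and richness never exceeds truth
  withr::local_seed(8)
  for (depth in c(2, 5, 50)) {
    sub <- subsample_repertoire(ct, depth = depth)
    expect_equal(sum(sub$templates), depth)
    expect_lte(nrow(sub), nrow(ct))
  }

  # observed richness is non-decreasing in depth in expectation
  m <- vapply(c(2, 5, 15),
              function(d) mean(observed_richness_mc(ct, d, 4000, seed = 3)),
              numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("replicate pairs carry the configured technical noise", {
  co <- simulate_cohort(simulation_params(n_subjects = 4000, seed = 17))$cohort

  # zero noise: both measurements identical, all differences exactly 0
  r0 <- simulate_replicates(co, noise_sd = 0, seed = 4)
  expect_identical(r0$D_1, r0$D_2)
  expect_equal(estimate_mae(r0), 0)

  # per-measurement sd 0.02 -> pair-difference sd 0.02 * sqrt(2)
  r <- simulate_replicates(co, noise_sd = 0.02, seed = 4)
  diffs <- log10(r$D_1 / r$S_1) - log10(r$D_2 / r$S_2)
  target <- 0.02 * sqrt(2)
  mc_se <- target / sqrt(2 * (nrow(r) - 1))
  expect_lt(abs(stats::sd(diffs) - target), 4 * mc_se)

  # reproducible from the seed
  expect_identical(r, simulate_replicates(co, noise_sd = 0.02, seed = 4))
})
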