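# Shared fixtures: all synthetic, built in code at test time.

# small cohort with diversity generated from the exact linear relation
# D = a*S - b*S_k plus additive Gaussian noise (unbiased for OLS recovery)
linear_cohort <- function(n, a = 0.825, b = 0.965, noise_sd_raw = 2e4,
                          seed = 1L) {
  params <- simulation_params(
    n_subjects = n, seed = seed,
    d_model = list(kind = "linear", a = a, b = b, noise_sd_dex = 0))
  co <- simulate_cohort(params)$cohort
  withr::with_seed(seed + 1L, {
    co$D <- pmax(round(a * co$S - b * co$S_1000 +
                         stats::rnorm(n, 0, noise_sd_raw)), 1)
  })
  add_derived_metrics(co)
}

# exact, noiseless linear cohort (integer-safe): D = 0.8*S - 1.0*S_1000
exact_cohort <- function(n = 60, seed = 2L) {
  params <- simulation_params(
    n_subjects = n, seed = seed,
    d_model = list(kind = "linear", a = 0.8, b = 1, noise_sd_dex = 0))
  co <- simulate_cohort(params)$cohort
  # regenerate D exactly from rounded S, S_1000 so the relation is exact
  co$S <- round(co$S / 10) * 10          # make 0.8*S integral
  co$S_1000 <- round(co$S_1000)
  co$D <- 0.8 * co$S - 1.0 * co$S_1000
  add_derived_metrics(co)
}

# random feasible (S, D, S_k) triple at roughly repertoire scale
random_large_triple <- function() {
  S <- floor(runif(1, 5e5, 3e6))
  D <- floor(runif(1, S / 20, S / 2))
  k <- sample(c(10, 100, 1000), 1)
  if (D <= k) return(list(S = S, D = D, S_k = S, k = k))
  # pick S_k between the proportional floor and the tail-feasible ceiling
  lo <- max(k, ceiling(S * k / D))
  hi <- max(lo, min(S - (D - k), ceiling(0.6 * S)))
  S_k <- floor(runif(1, lo, hi + 1))
  cl <- clamp_triple(S, D, S_k, k)
  list(S = cl$S, D = cl$D, S_k = cl$S_k, k = k)
}

expect_roundtrip <- function(S, D, S_k, k, profile = "even") {
  m <- compute_metrics(construct_counts(S, D, S_k, k, profile = profile),
                       k = k)
  expect_identical(unname(c(m$S, m$D, m[[paste0("S_", k)]])),
                   as.numeric(c(S, D, S_k)))
}

# widen a two-stratum (male/female) curve for side-by-side comparison
sex_curves_wide <- function(cur) {
  male <- as.data.frame(cur[cur$stratum == "male",
                            c("bin_low", "n", "median")])
  female <- as.data.frame(cur[cur$stratum == "female",
                              c("bin_low", "n", "median")])
  names(male)[2:3] <- c("n_male", "median_male")
  names(female)[2:3] <- c("n_female", "median_female")
  merge(male, female, by = "bin_low")
}
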