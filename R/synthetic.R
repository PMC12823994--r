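#' Check feasibility of an (S, D, S_k) metric triple
#'
#' A triple of repertoire size `S`, richness `D` and top-k mass `S_k` is
#' realisable by some clone table iff every clone can carry at least one
#' template and the smallest top-k clone is at least as large as the largest
#' tail clone. Concretely, for `D > k`: `S_k >= k`, `S - S_k >= D - k`, and
#' `floor(S_k / k) >= ceiling((S - S_k) / (D - k))`; for `D <= k` the top-k
#' block is the whole repertoire, forcing `S_k == S`.
#'
#' @param S,D,S_k,k Scalar integers.
#' @return `TRUE` if feasible, otherwise a string naming the violated
#'   constraint.
#' @export
triple_feasibility <- function(S, D, S_k, k) {
  if (S < 1) return("S must be >= 1")
  if (D < 1) return("D must be >= 1")
  if (k < 1) return("k must be >= 1")
  if (D > S) return("D > S: each clone needs at least one template")
  if (D <= k) {
    if (S_k != S) return("S_k must equal S when k >= D")
    return(TRUE)
  }
  if (S_k < k) return("S_k < k: each of the k top clones needs >= 1 template")
  if (S - S_k < D - k) return("S - S_k < D - k: each tail clone needs >= 1 template")
  if (S_k %/% k < ceiling((S - S_k) / (D - k))) {
    return("rank inversion: smallest top-k clone would be below the largest tail clone")
  }
  TRUE
}

# even split of `total` over `n` slots, sorted descending (counts differ by <= 1)
.even_counts <- function(total, n) {
  q <- total %/% n
  r <- total %% n
  rep(c(q + 1, q), c(r, n - r))
}

# largest-remainder integer allocation of `total` over weights `w`
.largest_remainder <- function(total, w) {
  raw <- total * w / sum(w)
  out <- floor(raw)
  short <- total - sum(out)
  if (short > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(short)]
    out[idx] <- out[idx] + 1
  }
  out
}

#' Count vector hitting an exact (S, D, S_k) target
#'
#' Numeric core of [construct_clone_table()]: returns a descending integer
#' count vector of length `D`, summing to `S`, whose top-k partial sum is
#' exactly `S_k`. The tail (`D - k` clones) always splits `S - S_k` as evenly
#' as possible; the top block is either `"even"` (counts differ by at most 1)
#' or `"geometric"` (geometrically decaying weights, repaired by moving mass
#' from the largest clones to any clone that would fall below the largest
#' tail clone).
#'
#' @param S,D,S_k,k Target metrics.
#' @param profile `"even"` or `"geometric"`.
#' @param decay Per-rank geometric decay factor in (0, 1), used by the
#'   `"geometric"` profile.
#' @return Integer-valued numeric vector, sorted decreasing.
#' @export
construct_counts <- function(S, D, S_k, k, profile = c("even", "geometric"),
                             decay = 0.995) {
  profile <- match.arg(profile)
  feas <- triple_feasibility(S, D, S_k, k)
  if (!isTRUE(feas)) {
    stop(sprintf("infeasible metric target (S=%s, D=%s, S_k=%s, k=%s): %s",
                 format(S), format(D), format(S_k), format(k), feas),
         call. = FALSE)
  }
  if (D <= k) {
    n_top <- D
    tail_counts <- numeric(0)
  } else {
    n_top <- k
    tail_counts <- .even_counts(S - S_k, D - k)
  }
  top_total <- if (D <= k) S else S_k
  if (profile == "even") {
    top_counts <- .even_counts(top_total, n_top)
  } else {
    w <- decay^(seq_len(n_top) - 1)
    top_counts <- .largest_remainder(top_total, w)
    floor_ct <- if (length(tail_counts)) tail_counts[1L] else 1
    deficit <- sum(pmax(floor_ct - top_counts, 0))
    if (deficit > 0) {
      top_counts <- pmax(top_counts, floor_ct)
      excess <- top_counts - floor_ct
      i <- 1L
      while (deficit > 0 && i <= n_top) {
        take <- min(excess[i], deficit)
        top_counts[i] <- top_counts[i] - take
        deficit <- deficit - take
        i <- i + 1L
      }
    }
    top_counts <- sort(top_counts, decreasing = TRUE)
  }
  c(top_counts, tail_counts)
}

#' Construct a clone table with exact target metrics
#'
#' Inverse of [compute_metrics()] on the (S, D, S_k) triple: the returned
#' table satisfies `S = sum(templates)`, `D = n` clones and top-k mass
#' exactly `S_k`, enabling exact round-trip tests and a synthetic-cohort
#' generator that targets metric distributions directly rather than modelling
#' clonal dynamics.
#'
#' @inheritParams construct_counts
#' @param subject_id Subject id attached to the result.
#' @param seed Optional integer; when given, the row order of the returned
#'   table is shuffled (metrics are order-invariant).
#' @return A [clone_table()].
#' @export
#' @examples
#' ct <- construct_clone_table(10, 3, 8, k = 2)
#' compute_metrics(ct, k = 2) # S = 10, D = 3, S_2 = 8
construct_clone_table <- function(S, D, S_k, k,
                                  profile = c("even", "geometric"),
                                  decay = 0.995,
                                  subject_id = "subject", seed = NULL) {
  counts <- construct_counts(S, D, S_k, k, profile = profile, decay = decay)
  ids <- sprintf("c%07d", seq_along(counts))
  ord <- seq_along(counts)
  if (!is.null(seed)) {
    ord <- withr::with_seed(seed, sample.int(length(counts)))
  }
  clone_table(ids[ord], counts[ord], subject_id = subject_id)
}

#' Project a metric triple onto the feasible set
#'
#' Rounds the inputs to integers, then repairs violations by adjusting `S_k`
#' first (raising it to the smallest rank-consistent value, or capping it so
#' every tail clone keeps one template) and `D` second (clamping into
#' `[1, S]`). Used by [simulate_cohort()] when sampled targets fall outside
#' the feasible region.
#'
#' @inheritParams triple_feasibility
#' @return List with elements `S`, `D`, `S_k` and logical `clamped`.
#' @export
clamp_triple <- function(S, D, S_k, k) {
  S0 <- max(round(S), 1)
  D0 <- min(max(round(D), 1), S0)
  Sk0 <- round(S_k)
  if (D0 <= k) {
    Sk1 <- S0
  } else {
    lo <- k
    hi <- S0 - (D0 - k)
    Sk1 <- min(max(Sk0, lo), hi)
    rank_ok <- function(v) (v %/% k) >= ceiling((S0 - v) / (D0 - k))
    if (!rank_ok(Sk1)) {
      # rank consistency is monotone in S_k: binary search the minimal fix
      a <- Sk1; b <- hi
      while (a < b) {
        mid <- (a + b) %/% 2
        if (rank_ok(mid)) b <- mid else a <- mid + 1
      }
      Sk1 <- a
    }
  }
  list(S = S0, D = D0, S_k = Sk1,
       clamped = (Sk1 != Sk0) || (D0 != round(D)) || (S0 != round(S)))
}

# top-j partial sum implied by the "even" construction profile, vectorised
.topj_from_triple <- function(S, D, S_k, k, j) {
  out <- numeric(length(S))
  whole <- D <= j
  out[whole] <- S[whole]
  flat <- !whole & D <= k # k >= D: the whole repertoire is one even block
  if (any(flat)) {
    q <- S[flat] %/% D[flat]; r <- S[flat] %% D[flat]
    out[flat] <- j * q + pmin(j, r)
  }
  top <- !whole & !flat & j <= k
  if (any(top)) {
    q <- S_k[top] %/% k; r <- S_k[top] %% k
    out[top] <- j * q + pmin(j, r)
  }
  mid <- !whole & !flat & j > k
  if (any(mid)) {
    qt <- (S[mid] - S_k[mid]) %/% (D[mid] - k)
    rt <- (S[mid] - S_k[mid]) %% (D[mid] - k)
    out[mid] <- S_k[mid] + (j - k) * qt + pmin(j - k, rt)
  }
  out
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults describe the cross-sectional adult cohort the analysis targets:
#' ages 20-80 (median near 50), 47% male, log-normal repertoire size with
#' median 518,618 templates, clonal-expansion percentage `P_1000` rising from
#' 10% at age 20 to 30% at age 80 and higher in males and CMV-positive
#' subjects, and diversity generated from the linear size/clonality relation
#' `D = a*S - b*S_1000` with coefficients 0.825 and 0.965 plus log-normal
#' intrinsic scatter. See the methods vignette for the provenance of each
#' default.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param k Top-k cutoff the clonality model targets (default 1000).
#' @param age_range Uniform age range in years.
#' @param male_frac,cmv_pos_frac,cmv_unknown_frac Covariate frequencies.
#' @param s_model Log-normal repertoire-size model: `median_log10` (dex),
#'   `sd` (dex, residual), `age_slope` (dex/year, centred at age 50),
#'   `male_offset`, `cmv_offset` (dex).
#' @param p1000_model Clonality model for the target `P_k` percentage:
#'   `value_at_20` (%), `age_slope` (%/year), `male_offset`, `cmv_offset`
#'   (%), `noise_sd` (%).
#' @param d_model Diversity model. `kind = "linear"`: `D = a*S - b*S_k`
#'   times `10^N(0, noise_sd_dex)` — covariates act on `D` only through `S`
#'   and `S_k`. `kind = "lognormal"`: `log10 D` drawn conditionally normal
#'   given `log10 S` with `median_log10`, `sd`, `corr_with_s`, plus
#'   `age_slope`, `male_offset`, `cmv_offset` direct covariate effects.
#' @param replicate_noise_sd Per-measurement technical noise on
#'   `log10(D/S)` (dex) used by [simulate_replicates()].
#' @param depth Optional sequencing depth for [subsample_repertoire()]
#'   post-processing; `NULL` treats `S` itself as the sequenced depth.
#' @param profile Rank-abundance profile passed to [construct_clone_table()].
#' @return A list of class `tcr_sim_params`.
#' @export
simulation_params <- function(
    n_subjects = 1000L,
    seed = 1L,
    k = 1000L,
    age_range = c(20, 80),
    male_frac = 0.47,
    cmv_pos_frac = 0.45,
    cmv_unknown_frac = 0,
    s_model = list(median_log10 = log10(518618), sd = 0.12,
                   age_slope = -0.005, male_offset = 0, cmv_offset = 0.10),
    p1000_model = list(value_at_20 = 10, age_slope = 20 / 60,
                       male_offset = 3, cmv_offset = 5, noise_sd = 4),
    d_model = list(kind = "linear", a = 0.825, b = 0.965,
                   noise_sd_dex = 0.0245),
    d_lognormal = list(median_log10 = log10(319802), sd = 0.12,
                       corr_with_s = 0.8, age_slope = -0.005,
                       male_offset = -0.05, cmv_offset = -0.02),
    replicate_noise_sd = 0.027 / sqrt(2),
    depth = NULL,
    profile = "even") {
  p <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
            k = as.integer(k), age_range = age_range, male_frac = male_frac,
            cmv_pos_frac = cmv_pos_frac, cmv_unknown_frac = cmv_unknown_frac,
            s_model = s_model, p1000_model = p1000_model, d_model = d_model,
            d_lognormal = d_lognormal,
            replicate_noise_sd = replicate_noise_sd, depth = depth,
            profile = profile)
  stopifnot(p$n_subjects >= 1, p$k >= 1,
            p$s_model$sd >= 0, p$p1000_model$noise_sd >= 0,
            p$replicate_noise_sd >= 0,
            is.null(depth) || depth >= 1)
  if (identical(p$d_model$kind, "lognormal")) {
    stopifnot(abs(p$d_lognormal$corr_with_s) <= 1, p$d_lognormal$sd >= 0)
  }
  class(p) <- "tcr_sim_params"
  p
}

#' Simulate a synthetic cohort of TCR repertoires
#'
#' Draws covariates (age, sex, CMV status), then per-subject metric targets:
#' `log10 S` from a covariate-shifted normal, a target clonality percentage
#' `P_k` from the clonality model, and diversity `D` from the configured
#' diversity model. Targets are projected onto the feasible (S, D, S_k) set
#' ([clamp_triple()]); if more than half the subjects need clamping the
#' parameter set is rejected as inconsistent. Metrics (including `S_10` and
#' `S_100` implied by the even rank-abundance profile) are exact by
#' construction; clone tables themselves are materialised only on request,
#' since a realistic subject carries hundreds of thousands of clones.
#'
#' @param params A [simulation_params()] object.
#' @param keep_tables Materialise per-subject clone tables via
#'   [construct_clone_table()] (intended for small cohorts).
#' @return List with elements `cohort` (a `tcr_cohort` tibble of true
#'   metrics joined with covariates), `covariates`, `clone_tables` (named
#'   list or `NULL`), `n_clamped`, and `params`.
#' @export
simulate_cohort <- function(params = simulation_params(),
                            keep_tables = FALSE) {
  stopifnot(inherits(params, "tcr_sim_params"))
  if (identical(params$profile, "geometric") && !keep_tables) {
    stop("profile = 'geometric' requires keep_tables = TRUE (S_10/S_100 are not analytic)",
         call. = FALSE)
  }
  n <- params$n_subjects
  k <- params$k
  withr::local_seed(params$seed)

  age <- stats::runif(n, params$age_range[1], params$age_range[2])
  sex <- ifelse(stats::runif(n) < params$male_frac, "male", "female")
  u <- stats::runif(n)
  cmv <- ifelse(u < params$cmv_pos_frac, "positive",
                ifelse(u < params$cmv_pos_frac + params$cmv_unknown_frac,
                       "unknown", "negative"))
  male <- as.numeric(sex == "male")
  cmvp <- as.numeric(cmv == "positive")

  sm <- params$s_model
  mu_s <- sm$median_log10 + sm$age_slope * (age - 50) +
    male * sm$male_offset + cmvp * sm$cmv_offset
  log10S <- mu_s + stats::rnorm(n, 0, sm$sd)
  S <- round(10^log10S)

  pm <- params$p1000_model
  P <- pm$value_at_20 + pm$age_slope * (age - 20) + male * pm$male_offset +
    cmvp * pm$cmv_offset + stats::rnorm(n, 0, pm$noise_sd)
  P <- pmin(pmax(P, 0.5), 90)
  S_k <- round(P / 100 * S)

  dm <- params$d_model
  if (identical(dm$kind, "linear")) {
    D <- (dm$a * S - dm$b * S_k) * 10^stats::rnorm(n, 0, dm$noise_sd_dex)
    D <- pmax(round(D), 1)
  } else if (identical(dm$kind, "lognormal")) {
    dl <- params$d_lognormal
    mu_d <- dl$median_log10 + dl$age_slope * (age - 50) +
      male * dl$male_offset + cmvp * dl$cmv_offset
    cond_mu <- mu_d + dl$corr_with_s * (dl$sd / max(sm$sd, .Machine$double.eps)) *
      (log10S - mu_s)
    cond_sd <- dl$sd * sqrt(1 - dl$corr_with_s^2)
    D <- pmax(round(10^(cond_mu + stats::rnorm(n, 0, cond_sd))), 1)
  } else {
    stop(sprintf("unknown d_model kind '%s'", dm$kind), call. = FALSE)
  }

  clamped <- logical(n)
  for (i in seq_len(n)) {
    cl <- clamp_triple(S[i], D[i], S_k[i], k)
    S[i] <- cl$S; D[i] <- cl$D; S_k[i] <- cl$S_k
    clamped[i] <- cl$clamped
  }
  n_clamped <- sum(clamped)
  if (n_clamped > n / 2) {
    stop(sprintf(
      "inconsistent simulation parameters: %d of %d subjects (%.0f%%) required feasibility clamping",
      n_clamped, n, 100 * n_clamped / n), call. = FALSE)
  }

  sid <- sprintf("sim%05d", seq_len(n))
  covariates <- tibble::tibble(subject_id = sid, age = age, sex = sex,
                               cmv_status = cmv)
  metrics <- tibble::tibble(
    subject_id = sid, S = S, D = D,
    S_10 = .topj_from_triple(S, D, S_k, k, 10),
    S_100 = .topj_from_triple(S, D, S_k, k, 100)
  )
  metrics[[paste0("S_", k)]] <- S_k

  clone_tables <- NULL
  if (keep_tables) {
    clone_tables <- vector("list", n)
    names(clone_tables) <- sid
    for (i in seq_len(n)) {
      clone_tables[[i]] <- construct_clone_table(
        S[i], D[i], S_k[i], k, profile = params$profile, subject_id = sid[i])
    }
    if (identical(params$profile, "geometric")) {
      for (i in seq_len(n)) {
        m <- compute_metrics(clone_tables[[i]], k = c(10L, 100L))
        metrics$S_10[i] <- m$S_10
        metrics$S_100[i] <- m$S_100
      }
    }
  }

  cohort <- add_derived_metrics(
    dplyr::inner_join(metrics, covariates, by = "subject_id"))
  list(cohort = cohort, covariates = covariates, clone_tables = clone_tables,
       n_clamped = n_clamped, params = params)
}

#' Multinomial subsampling of a repertoire to a target sequencing depth
#'
#' Models finite sequencing depth: draws `depth` templates with probabilities
#' proportional to the clone counts, either with replacement (multinomial,
#' the default) or without (multivariate hypergeometric, exhaustive at
#' `depth == S`). Clones drawn zero times are dropped, so observed richness
#' can only fall.
#'
#' @param table A [clone_table()].
#' @param depth Number of templates to draw.
#' @param seed Optional integer seed.
#' @param replace Draw with replacement (default `TRUE`).
#' @return A [clone_table()] whose total template count equals `depth`.
#' @export
subsample_repertoire <- function(table, depth, seed = NULL, replace = TRUE) {
  stopifnot(inherits(table, "tcr_clone_table"), depth >= 1)
  counts <- table$templates
  total <- sum(counts)
  draw <- function() {
    if (replace) {
      as.numeric(stats::rmultinom(1, depth, counts / total))
    } else {
      if (depth > total) {
        stop(sprintf("depth (%s) exceeds total templates (%s) for sampling without replacement",
                     format(depth), format(total)), call. = FALSE)
      }
      # sequential multivariate hypergeometric
      out <- numeric(length(counts))
      rem_total <- total
      rem_depth <- depth
      for (i in seq_along(counts)) {
        if (rem_depth == 0) break
        x <- stats::rhyper(1, counts[i], rem_total - counts[i], rem_depth)
        out[i] <- x
        rem_total <- rem_total - counts[i]
        rem_depth <- rem_depth - x
      }
      out
    }
  }
  new_counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  keep <- new_counts > 0
  clone_table(table$clone_id[keep], new_counts[keep],
              subject_id = subject_id(table))
}

#' Monte-Carlo observed richness under multinomial subsampling
#'
#' Repeats the with-replacement draw of [subsample_repertoire()] `n_draws`
#' times and returns the observed richness (number of distinct clones drawn)
#' of each draw, for comparison against exact enumeration values.
#'
#' @param table A [clone_table()].
#' @param depth Sequencing depth per draw.
#' @param n_draws Number of independent draws.
#' @param seed Optional integer seed.
#' @return Integer vector of length `n_draws`.
#' @export
observed_richness_mc <- function(table, depth, n_draws, seed = NULL) {
  stopifnot(inherits(table, "tcr_clone_table"), depth >= 1, n_draws >= 1)
  p <- table$templates / sum(table$templates)
  f <- function() stats::rmultinom(n_draws, depth, p)
  x <- if (is.null(seed)) f() else withr::with_seed(seed, f())
  colSums(x > 0)
}

#' Simulate paired technical replicate measurements
#'
#' For each subject, produces two independent measurements of (S, D) whose
#' `log10(D/S)` values carry additive Gaussian technical noise of standard
#' deviation `noise_sd` per measurement, so the within-pair difference in
#' `log10(D/S)` has standard deviation `noise_sd * sqrt(2)`. This is the
#' generative model against which [estimate_mae()] is calibrated.
#'
#' @param cohort A cohort tibble with columns `subject_id`, `S`, `D`, or a
#'   list of [clone_table()]s (metrics are computed first).
#' @param noise_sd Per-measurement noise on `log10(D/S)` in dex.
#' @param seed Optional integer seed.
#' @return Tibble with columns `subject_id`, `S_1`, `D_1`, `S_2`, `D_2`.
#' @export
simulate_replicates <- function(cohort, noise_sd, seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (is.list(cohort) && !is.data.frame(cohort)) {
    cohort <- dplyr::bind_rows(lapply(cohort, compute_metrics))
  }
  stopifnot(all(c("subject_id", "S", "D") %in% names(cohort)))
  n <- nrow(cohort)
  gen <- function() {
    eps <- matrix(stats::rnorm(2L * n, 0, noise_sd), ncol = 2L)
    d1 <- pmin(pmax(round(cohort$D * 10^eps[, 1L]), 1), cohort$S)
    d2 <- pmin(pmax(round(cohort$D * 10^eps[, 2L]), 1), cohort$S)
    tibble::tibble(subject_id = cohort$subject_id,
                   S_1 = cohort$S, D_1 = d1,
                   S_2 = cohort$S, D_2 = d2)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
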