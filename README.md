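# tcrdiv

Analysis of what determines T cell receptor (TCRβ) repertoire diversity, for
immunologists and biostatisticians working with bulk immunosequencing data.

A blood sample's TCRβ repertoire is summarised by three numbers: the
repertoire size *S* (total productive templates sequenced), the diversity
*D* (richness: number of unique clonotypes), and the mass of the most
expanded clones, *S*₁₀₀₀ (templates carried by the 1,000 most abundant
clones; as a percentage, *P*₁₀₀₀ = 100 · *S*₁₀₀₀ / *S*). Across adult
cohorts, *D* declines with age, is lower in males, and responds to chronic
CMV infection — but almost all of that structure is mediated by *S* and
*S*₁₀₀₀. `tcrdiv` implements the full analysis chain that demonstrates and
quantifies this:

- **Repertoire metrics** from AIRR-style or simple two-column clone tables:
  *S*, *D*, *S*ₖ, *P*ₖ (all logs base 10).
- **Descriptive cohort structure**: binned-median age curves with percentile
  bootstrap CIs, stratified by sex and CMV status, with central 50%/90%
  bands; conditional median grids (e.g. median log₁₀ *D* vs age in bins of
  log₁₀ *S* or *P*₁₀₀₀); Spearman rank correlations with mid-rank ties.
- **Predictive models**: a gradient-boosted regressor (xgboost, default
  hyperparameters, squared-error loss) with five-fold cross-validation and
  feature importances, and the no-intercept linear model

  *D̂* = *a*·*S* − *b*·*S*₁₀₀₀

  fit on untransformed values, with pairs-bootstrap coefficient errors,
  held-out *R*², and sensitivity to the top-k cutoff (k = 10, 100, 1000).
- **Variance decomposition**: the measurement floor σₘ (MAE) estimated as
  the sd of within-pair differences in log₁₀(*D*/*S*) over technical
  replicates, subtracted in quadrature from the model residual scatter σᵣ
  to leave the intrinsic biological scatter σᵢ = √(σᵣ² − σₘ²).
- **A constructive synthetic-cohort generator** that hits exact
  (*S*, *D*, *S*ₖ) targets per subject under configurable age/sex/CMV effect
  models, with multinomial sequencing subsampling and paired-replicate
  simulation — the test bed for every stage above.

## Worked example

```r
library(tcrdiv)

compute_metrics(clone_table(c("c1", "c2", "c3"), c(5, 3, 2)), k = 2)
#> # A tibble: 1 × 7
#>   subject_id     S     D   S_2   P_2 log10_S log10_D
#> 1 subject       10     3     8    80       1   0.477

params <- simulation_params(n_subjects = 2000, seed = 1)
sim <- simulate_cohort(params)
pairs <- simulate_replicates(sim$cohort, noise_sd = params$replicate_noise_sd,
                             seed = 2)
cohort <- sim$cohort
cohort$D <- pairs$D_1            # analyse one measured replicate
cohort <- add_derived_metrics(cohort)

fit_linear_model(cohort, seed = 3)
#> Linear diversity model (k = 1000, n = 2000)
#>   D_hat = (0.825 +/- 0.004) * S - (0.952 +/- 0.016) * S_1000
#>   CV R^2 (raw) = 0.971, CV R^2 (log10) = 0.973
#>   residual sd = 0.0308 dex (28358 raw)

decompose_variance(fit_linear_model(cohort, seed = 3), pairs)
#> Variance decomposition of diversity residual scatter (dex)
#>   sigma_r (model residual)      = 0.031
#>   sigma_m (measurement, MAE)    = 0.027
#>   sigma_i (intrinsic, quadrature) = 0.015
#>   unexplained: 1 - CV R^2 = 0.029; (sigma_i/sigma_total)^2 = 0.0065
```

Reading: size and top-clone mass explain ~97% of the variance in measured
diversity; of the 0.031 dex residual scatter, 0.027 dex is the measurement
floor estimated from replicates, leaving 0.015 dex of intrinsic biological
scatter.

## Analysis workflow

The `analysis/` scripts run the full study on the synthetic cohort and
write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # cohort + replicates (+ demo clone tables)
Rscript analysis/02_repertoire_metrics.R # recompute metrics from raw tables
Rscript analysis/03_stratified_curves.R  # age curves, grids, correlations
Rscript analysis/04_fit_models.R         # GBM + linear model + top-k table
Rscript analysis/05_error_decomposition.R
```

Real deposited repertoire-metric tables drop in after a column rename to
the documented schema (`subject_id, age, sex, cmv_status, S, D, S_10,
S_100, S_1000`); see `inst/extdata/synthetic_metrics_deposited_style.csv`
for a synthetic fixture in a deposited-style schema and
`read_cohort_table()` for the contract.

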