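#!/usr/bin/env Rscript

# Stage 5: split the linear model's residual scatter into measurement and
# intrinsic components.
#
# The paired technical replicates give the measurement floor (MAE) as the
# sd of within-pair differences in log10(D/S); subtracting it in quadrature
# from the model residual sd leaves the intrinsic biological scatter.

suppressPackageStartupMessages(library(tcrdiv))

cohort <- read_cohort_table("results/cohort/cohort_observed.csv")
pairs <- readr::read_csv("results/cohort/replicate_pairs.csv",
                         show_col_types = FALSE)

fit <- fit_linear_model(cohort, k = 1000L, n_boot = 200L, seed = 20260402L)
dec <- decompose_variance(fit, pairs)
print(dec)

dir.create("results/models", showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(unclass(dec), "results/models/decomposition.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("wrote results/models/decomposition.json\n")
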