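#!/usr/bin/env Rscript

# Stage 3: descriptive cohort structure.
#
# Binned-median age curves of log10 D, log10 S and P_1000 stratified by sex
# and by CMV status (with bootstrap CIs and central 50%/90% bands),
# conditional median grids of log10 D given size and clonality, and the
# rank correlation between size and clonality by CMV stratum.

suppressPackageStartupMessages(library(tcrdiv))

cohort <- read_cohort_table("results/cohort/cohort_observed.csv")
out <- "results/curves"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (yv in c("log10_D", "log10_S", "P_1000")) {
  for (strat in c("sex", "cmv_status")) {
    cur <- stratified_curves(cohort, y = yv, stratify_by = strat,
                             n_boot = 1000, seed = 20260301L)
    readr::write_csv(cur, file.path(out, sprintf("%s_by_%s.csv", yv, strat)))
  }
}
cat("wrote stratified age curves for log10_D, log10_S, P_1000\n")

sex_dm <- readr::read_csv(file.path(out, "log10_D_by_sex.csv"),
                          show_col_types = FALSE)
for (st in unique(sex_dm$stratum)) {
  sub <- sex_dm[sex_dm$stratum == st, ]
  cat(sprintf("  median log10 D (%s): %s\n", st,
              paste(sprintf("%.3f", sub$median), collapse = " ")))
}

# log10 D vs age within quartile bins of log10 S, and of P_1000
s_edges <- quantile(cohort$log10_S, c(0, .25, .5, .75, 1), names = FALSE)
grid_s <- conditional_median_grid(cohort, y = "log10_D", x = "age",
                                  condition_on = "log10_S",
                                  condition_edges = s_edges,
                                  x_edges = seq(20, 80, 10),
                                  n_boot = 200, seed = 20260302L)
readr::write_csv(grid_s, file.path(out, "log10_D_vs_age_in_log10_S_bins.csv"))
p_edges <- quantile(cohort$P_1000, c(0, .25, .5, .75, 1), names = FALSE)
grid_p <- conditional_median_grid(cohort, y = "log10_D", x = "age",
                                  condition_on = "P_1000",
                                  condition_edges = p_edges,
                                  x_edges = seq(20, 80, 10),
                                  n_boot = 200, seed = 20260303L)
readr::write_csv(grid_p, file.path(out, "log10_D_vs_age_in_P_1000_bins.csv"))
cat("wrote conditional median grids (size and clonality conditioning)\n")

for (cm in c("negative", "positive")) {
  sub <- cohort[cohort$cmv_status == cm, ]
  sp <- spearman_correlation(sub$log10_S, sub$P_1000)
  cat(sprintf("  Spearman rho(log10 S, P_1000) | CMV %s: %.3f (n = %d, p = %.3g)\n",
              cm, sp$rho, sp$n, sp$p_value))
}

# figures, when ggplot2 is available
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  g <- ggplot(sex_dm[!sex_dm$flagged, ],
              aes(bin_mid, median, colour = stratum)) +
    geom_ribbon(aes(ymin = q25, ymax = q75, fill = stratum), alpha = 0.2,
                colour = NA) +
    geom_pointrange(aes(ymin = ci_low, ymax = ci_high)) +
    geom_line() +
    labs(x = "age (years)", y = "median log10 D",
         title = "TCRβ diversity vs age, by sex") +
    theme_minimal()
  ggsave("results/figures/log10_D_by_sex.png", g, width = 6, height = 4,
         dpi = 150)
  cat("wrote results/figures/log10_D_by_sex.png\n")
}
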