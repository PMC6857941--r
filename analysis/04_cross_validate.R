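#!/usr/bin/env Rscript
# Step 4: leave-one-out cross-validation of the fitted model.
#
# Each panel member in the fit set is removed in turn, the constants are
# re-estimated on the remainder, and the excluded variant's relative
# capacity is predicted from the refitted model. The predicted-vs-observed
# pairs are summarized by Pearson's correlation with its two-sided t-based
# p-value; a scatter with the OLS line is written when ggplot2 is present.

suppressMessages(library(ugtcap))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20260925L

summaries <- read_summary_csv("results/panel/docking_summaries.csv")
capacities <- read_capacity_csv("results/panel/capacities.csv")
panel <- capacity_panel(summaries, capacities, ligand = "synthetic")

loo <- loo_cross_validate(panel, fit_control(n_starts = 20, seed = seed))
print(loo)
corr <- loo$correlation
cat(sprintf("regression of in vitro on in silico: slope %.3f, intercept %.2f\n",
            corr$slope, corr$intercept))
cat(sprintf("significant at 0.05: %s\n", if (corr$p < 0.05) "yes" else "no"))

write_result_csv(loo$folds, "results/loo_folds.csv", seed = seed)
cat("wrote results/loo_folds.csv\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  ggplot2::ggsave("results/figures/loo_scatter.png", plot_cv(loo),
                  width = 5, height = 4, dpi = 150)
  cat("wrote results/figures/loo_scatter.png\n")
}
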