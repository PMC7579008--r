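#!/usr/bin/env Rscript
# Stage 5 — diagnostic figures.
#
# Importance bar chart, binned predictor-exceedance panels for the six
# mechanistic predictors, and both cutoff-determination curve plots, saved
# under results/figures/.

suppressPackageStartupMessages({
  library(ashazard)
  library(ggplot2)
})

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

imp <- read.csv("results/importance.csv")
ggsave("results/figures/importance.png", plot_importance(imp),
       width = 7, height = 6, dpi = 150)

table <- read.csv("results/modeling_table.csv")
ggsave("results/figures/binned_correlations.png",
       plot_binned_correlation(table,
                               predictors = sprintf("cont_%02d", 1:6)),
       width = 9, height = 6, dpi = 150)

for (crit in c("sens_spec", "ppv_npv")) {
  cv <- read.csv(sprintf("results/cutoff_curves_%s.csv", crit))
  a <- if (crit == "sens_spec") abs(cv$sensitivity - cv$specificity)
  else abs(cv$ppv - cv$npv)
  a[c(1, nrow(cv))] <- NA
  res <- structure(list(cutoff = cv$cutoff[which.min(a)], criterion = crit,
                        accuracy_at_cutoff = cv$accuracy[which.min(a)],
                        curves = cv), class = "cutoff_result")
  ggsave(sprintf("results/figures/cutoff_%s.png", crit),
         plot_cutoff_curves(res), width = 6, height = 4, dpi = 150)
}
cat("figures written to results/figures/\n")
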