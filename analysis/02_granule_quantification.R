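#!/usr/bin/env Rscript
# Imaging arm: flat-field correction, RNA segmentation, per-cell granularity
# statistics and the one-sided condition comparisons. Uses the simulator
# directly (same templates as 01_simulate_images.R) so the run is
# self-contained and reproducible from the seed.

library(mitogranule)

dir.create("results", showWarnings = FALSE)
seed_base <- 100

ctrl <- image_sim_params(granular = FALSE, seed = 0)
trt <- image_sim_params(granular = TRUE, decay_factor = 0.6, seed = 0)
res <- quantify_condition_pair(ctrl, trt, n_fields = 6, seed_base = seed_base)

write_table_csv(res$metrics, "results/cell_metrics.csv",
                provenance = paste0("seed_base=", seed_base))
write_table_csv(res$comparisons, "results/condition_comparisons.csv",
                provenance = paste0("seed_base=", seed_base))

cat("per-cell metrics:", nrow(res$metrics), "cells\n")
med <- aggregate(cbind(frac_area_occupied, skewness, norm_intensity)
                 ~ condition, res$metrics, median)
print(med, digits = 3)
cat("\nOne-sided tests (treated = granular vs control = diffuse):\n")
print(res$comparisons, digits = 3)

dir.create("results/figures", showWarnings = FALSE)
ggplot2::ggsave("results/figures/frac_area_occupied.png",
                plot_metric_by_condition(res$metrics, "frac_area_occupied"),
                width = 4, height = 4, dpi = 150)
ggplot2::ggsave("results/figures/skewness.png",
                plot_metric_by_condition(res$metrics, "skewness",
                                         log10 = FALSE),
                width = 4, height = 4, dpi = 150)
cat("\nThe granular condition occupies less cellular area and is more\n")
cat("right-skewed, the signature of RNA clustering into granules.\n")
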