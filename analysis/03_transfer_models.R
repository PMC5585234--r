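#!/usr/bin/env Rscript
# Stage 3 — calibrate the transfer functions on the modern world.
#
# Selects the IKFA factor count by minimum leave-one-out RMSE over k = 2..8,
# fits the factor-analysis transfer function for mean SST and STV, trains
# the neural-network ensembles (5 hidden units, 1000 replicates, median
# aggregation), and reports the internal (resubstitution) validation that
# mirrors testing the method on the data that built it. Run stages 01-02
# first.

library(coralclim)

asm_dir <- file.path("results", "assemblages")
out_dir <- file.path("results", "models")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

field <- read_field(file.path("results", "world", "modern_field.csv"))
modern <- read_assemblage(file.path(asm_dir, "modern_species.csv"))
cal <- pair_cells(modern, field)

# factor-count selection by leave-one-out RMSE
ks <- 2:8
loo_rmse <- vapply(ks, function(k) {
  cross_validation(cal, "mean_sst", method = "ikfa",
                   mode = "leave_one_out", k = k)$rmse
}, numeric(1))
k_best <- ks[which.min(loo_rmse)]
cat("IKFA leave-one-out RMSE by k:\n")
print(data.frame(k = ks, loo_rmse = round(loo_rmse, 4)), row.names = FALSE)
cat(sprintf("Selected k = %d.\n", k_best))

for (env in c("mean_sst", "stv")) {
  m <- fit_ikfa(cal, env, k = k_best)
  write_ikfa(m, file.path(out_dir, paste0("ikfa_", env, ".json")))
  cat(sprintf("IKFA %s: calibration RMSE %.3f C.\n", env, m$calibration$rmse))

  cfg <- ann_config(n_replicates = 1000, base_seed = 42L)
  iv <- internal_validation(cal, env, cfg)
  write_ensemble(iv$ensemble, file.path(out_dir, paste0("ann_", env, ".json")))
  cat(sprintf(
    "ANN %s: %d replicates, median internal deviation %+.4f C (IQR of cell medians %.3f C).\n",
    env, length(iv$ensemble$replicates), iv$median_deviation,
    IQR(iv$deviations$deviation)))
  dev_path <- file.path(out_dir, paste0("internal_validation_", env, ".csv"))
  write.csv(iv$deviations, dev_path, row.names = FALSE)
}
writeLines(as.character(k_best), file.path(out_dir, "k_selected.txt"))
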