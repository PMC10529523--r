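#!/usr/bin/env Rscript
# Stage 3: nodule-level cystic-percentage estimation.
#
# Aggregates the held-out (grouped cross-validated) patch predictions into
# per-nodule cystic percentages, compares them with the phantom truth, and
# appends the DSS column to the synthetic observer table from stage 01.

suppressMessages(library(sonocyst))

seed <- 11L
cfg <- run_config(seed = seed)
dir.create("results", showWarnings = FALSE)

suite <- synthesize_nodule_suite(n = 20L, seed = seed,
                                 pixel_spacing_mm = cfg$pixel_spacing_mm)
res <- recover_cystic_suite(suite, cfg, seed = seed)

write_estimates_csv(res$per_nodule, "results/cystic_estimates.csv")
cat(sprintf("nodule-level MAE: %.2f percentage points over %d nodules\n",
            res$mae_points, nrow(res$per_nodule)))

obs_path <- "results/observer_table_synthetic.csv"
if (file.exists(obs_path)) {
  obs <- read.csv(obs_path)
  obs$DSS <- res$per_nodule$estimated_pct[match(obs$nodule_id,
                                                res$per_nodule$nodule_id)]
  write.csv(obs, obs_path, row.names = FALSE)
  cat("appended DSS column to", obs_path, "\n")
} else {
  cat("run analysis/01_simulate.R first to get the observer table\n")
}
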