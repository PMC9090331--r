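#!/usr/bin/env Rscript
# Spreading study on a synthetic control cohort: onset alignment, area and
# volume fits, initial fluxes, speed terciles and the flux regression; then
# the across-condition comparison of early volume loss.

suppressPackageStartupMessages(library(osmovol))
seed <- 1

cfg <- study_config(preset = "control", n_cells = 40,
                    out_dir = "results/03_spreading", seed = seed)
res <- run_study(cfg)
cells <- res$cells

cat(sprintf("Control cohort: %d cells fitted, %d excluded at onset\n",
            nrow(cells), length(res$excluded)))
cat(sprintf("  tercile sizes: %s\n",
            paste(table(cells$group), collapse = "/")))
cat(sprintf("  median tau_a %.1f min, median xi %.2f, median tau %.1f min\n",
            median(cells$tau_a, na.rm = TRUE),
            median(cells$xi, na.rm = TRUE),
            median(cells$tau, na.rm = TRUE)))
cat(sprintf("  flux regression: dV/dt = %.3f dA/dt + %.3f (R^2 %.2f)\n",
            res$regression$slope, res$regression$intercept,
            res$regression$r_squared))
cat("  (faster-spreading cells lose volume faster: negative slope)\n")

# per-group mean fluxes, the tercile summary
by_grp <- aggregate(cbind(dAdt, dVdt) ~ group, cells, mean)
write.csv(by_grp, "results/03_spreading/tercile_fluxes.csv",
          row.names = FALSE)
cat("\nMean initial fluxes by speed tercile:\n")
print(by_grp, row.names = FALSE)

# across-condition early volume loss (noise-free forward cohorts)
loss_of <- function(preset) {
  cfgp <- condition_preset(preset, n_cells = 15, seed = 91,
                           noise_cv = 0, population_scale_cv = 0,
                           duration = 25)
  coh <- generate_spreading_cohort(cfgp)
  mean(sapply(split(coh$trajectories, coh$trajectories$cell_id),
              function(cell) {
    post <- cell[cell$time_min >= cfgp$pre_onset_min &
                   cell$time_min <= cfgp$pre_onset_min + 20, ]
    1 - min(post$volume_um3) / post$volume_um3[1]
  }))
}
presets <- c("uncoupled", "slow", "control", "fast")
losses <- data.frame(condition = presets,
                     mean_20min_loss = sapply(presets, loss_of))
cat("\nMean 20-min volume loss by condition (fast spreading loses most;\n")
cat("decoupling ion transport from tension abolishes the loss):\n")
print(losses, row.names = FALSE)
write.csv(losses, "results/03_spreading/condition_losses.csv",
          row.names = FALSE)
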