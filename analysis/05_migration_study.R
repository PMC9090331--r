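#!/usr/bin/env Rscript
# Migration study: volume fluctuations of cells migrating through a fibrous
# matrix. Faster cells are deformed at higher frequency and show larger
# windowed volume-flux fluctuations; the transfer-function model is fitted
# back to the (speed, CV) scatter.

suppressPackageStartupMessages(library(osmovol))
dir.create("results", showWarnings = FALSE)
seed <- 1

mp <- migration_params(forcing_amplitude = 0.1, mesh_spacing = 50,
                       xi = 1, tau = 30, tau_eff = 40)
set.seed(seed)
speeds <- runif(43, 0.05, 1.8)
tracks <- generate_migration_tracks(mp, speeds, duration_min = 180,
                                    noise_cv = 0.002, seed = seed)

cv <- sapply(split(tracks, tracks$cell_id), windowed_flux_cv)
per_cell <- data.frame(cell_id = names(cv),
                       speed = tracks$speed[match(names(cv),
                                                  tracks$cell_id)],
                       cv = cv)
per_cell$group <- cut(per_cell$speed, c(-Inf, 0.5, 1, Inf),
                      labels = c("<0.5", "0.5-1", ">1"))
by_grp <- aggregate(cv ~ group, per_cell, mean)
cat("Mean windowed volume-flux CV by speed group (um/min):\n")
print(by_grp, row.names = FALSE)
cat("  faster-moving cells show the larger volume fluctuations\n\n")

# The windowed-slope estimator filters a sinusoidal fluctuation by a known
# factor omega*T*H(omega T/2), H(x) = 3 (sin x - x cos x)/x^3: correct the
# empirical CVs back to the continuous-time fluctuation scale before
# fitting the transfer-function model.
Tw <- 10
omega <- 2 * pi * per_cell$speed / mp$mesh_spacing
x <- omega * Tw / 2
H <- ifelse(x > 0, 3 * (sin(x) - x * cos(x)) / x^3, 1)
per_cell$cv_corr <- per_cell$cv / (omega * Tw * H)

fit <- fit_migration_cv(per_cell$speed, per_cell$cv_corr, mesh_spacing = 50)
amp_true <- mp$xi * mp$forcing_amplitude * mp$tau
cat(sprintf("Transfer-function fit (n = %d): amplitude xi*eps*tau = %.2f min (truth %.2f),\n",
            fit$n, fit$amp, amp_true))
cat(sprintf("  tau_eff = %.1f min (truth %.1f), residual norm %.3g\n",
            fit$tau_eff, mp$tau_eff, fit$residual_norm))
cat(sprintf("  saturation ratio amp/tau_eff = %.4f (truth %.4f): the high-speed\n",
            fit$amp / fit$tau_eff, amp_true / mp$tau_eff))
cat("  plateau is well identified from track data; the individual parameters\n")
cat("  are only weakly identified because most cells sit in the saturated\n")
cat("  regime omega*tau_eff > 1 (cleaner separation needs slower cells).\n")

write.csv(per_cell, "results/05_migration_cv.csv", row.names = FALSE)
write.csv(data.frame(parameter = c("amp_min", "tau_eff_min"),
                     estimate = c(fit$amp, fit$tau_eff),
                     truth = c(mp$xi * mp$forcing_amplitude * mp$tau,
                               mp$tau_eff)),
          "results/05_migration_fit.csv", row.names = FALSE)
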