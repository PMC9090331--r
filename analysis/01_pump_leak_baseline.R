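#!/usr/bin/env Rscript
# Baseline pump-and-leak analysis: the calibrated steady state, the passive
# (Ponder) response curve, and the order-of-magnitude pressure estimates
# that bound what cortical contractility can do to cell volume.

suppressPackageStartupMessages(library(osmovol))
dir.create("results", showWarnings = FALSE)

p <- default_ion_params()
ss <- solve_steady_state(p)

cat("== Pump-and-leak steady state (default calibration) ==\n")
cat(sprintf("  V = %.1f um^3 (water %.1f, excluded %.1f)\n", ss$V, ss$Vw, ss$b))
cat(sprintf("  interior: Na %.1f, K %.1f, Cl %.1f mM  (ions %.0f mM)\n",
            ss$cNa, ss$cK, ss$cCl, ss$cNa + ss$cK + ss$cCl))
cat(sprintf("  impermeant osmolytes: %.0f mM, membrane potential %.1f mV\n",
            (p$nX + p$nY) / ss$Vw, ss$Vm))

write.csv(data.frame(quantity = c("V_um3", "Vw_um3", "cNa_mM", "cK_mM",
                                  "cCl_mM", "Vm_mV", "impermeant_mM"),
                     value = c(ss$V, ss$Vw, ss$cNa, ss$cK, ss$cCl, ss$Vm,
                               (p$nX + p$nY) / ss$Vw)),
          "results/01_steady_state.csv", row.names = FALSE)

# Passive response curve: volume right after a shock, before any regulation
ratios <- seq(0.4, 2, by = 0.05)
ponder <- data.frame(piso_over_p = ratios,
                     v_over_viso = ponder_passive_volume(ratios, 0.67))
write.csv(ponder, "results/01_ponder_curve.csv", row.names = FALSE)
cat(sprintf("\n== Ponder curve: slope %.2f (active fraction), intercept %.2f ==\n",
            0.67, 0.33))

# Order-of-magnitude mechanics: why contractility cannot set the volume
Pi_total <- 1e5           # Pa; ~100 mM impermeant osmolytes
P_laplace <- laplace_pressure(1, 10)
dPi_10pc <- trapped_pressure_change(Pi_total, 0.10)
bound10 <- contractility_volume_bound(10, 100, Pi_total)
cat("\n== Pressure scales ==\n")
cat(sprintf("  Laplace pressure (1 mN/m, r = 10 um): %.0f Pa\n", P_laplace))
cat(sprintf("  10%% volume loss raises trapped-osmolyte pressure by %.0f Pa",
            dPi_10pc$linearized))
cat(sprintf(" (exact: %.0f Pa)\n", dPi_10pc$exact))
cat(sprintf("  10x contractility moves volume by %.1f%% only\n", 100 * bound10))
write.csv(data.frame(quantity = c("laplace_Pa", "trapped_dP_lin_Pa",
                                  "trapped_dP_exact_Pa",
                                  "contractility_bound_pct"),
                     value = c(P_laplace, dPi_10pc$linearized,
                               dPi_10pc$exact, 100 * bound10)),
          "results/01_pressure_scales.csv", row.names = FALSE)

# Apparent osmotic bulk modulus from a small passive shock
ratio <- 1.01
dV <- 2000 * (ponder_passive_volume(ratio, 0.67) - 1)
dP <- 300 * p$RT * (1 - 1 / ratio)
cat(sprintf("\n  osmotic bulk modulus (small shock): %.2e Pa\n",
            bulk_modulus(2000, dP, dV)))
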