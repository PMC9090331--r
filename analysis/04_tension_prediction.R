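#!/usr/bin/env Rscript
# Model prediction: how much higher membrane tension would transiently rise
# during spreading if the mechano-osmotic coupling were absent, across
# spreading speeds. The largest excess is expected for the fastest cells.

suppressPackageStartupMessages(library(osmovol))
dir.create("results", showWarnings = FALSE)

# dimensionless stiffness k*Atot_iso/gamma_iso = 100 for this prediction
gamma_iso <- 0.4                      # mN/m
Atot_iso <- sphere_area_from_volume(2000)
k <- 100 * gamma_iso / Atot_iso
alpha <- -0.01                        # gives xi = 1 with this stiffness
p <- mechano_params(alpha = alpha, k = k, gamma_iso = gamma_iso,
                    Atot_iso = Atot_iso, tau = 15, r_growth = 0.05,
                    V_iso = 2000)
cat(sprintf("Coupling parameters: xi = %.2f, tau = %.0f min, k Atot/gamma = 100\n\n",
            p$xi, p$tau))

rows <- lapply(c(fast = 4, control = 15, slow = 35), function(tau_a) {
  anz <- spreading_ansatz(50, 1200, tau_a)
  td <- tension_difference_without_coupling(p, anz, duration = 120, dt = 0.1)
  data.frame(tau_a = tau_a,
             peak_diff = max(td$diff),
             t_peak_min = td$time_min[which.max(td$diff)],
             end_diff = abs(tail(td$diff, 1)))
})
out <- do.call(rbind, rows)
out$condition <- rownames(out)
cat("Peak excess relative tension (uncoupled minus coupled):\n")
print(out[, c("condition", "tau_a", "peak_diff", "t_peak_min", "end_diff")],
      row.names = FALSE)
cat("\nFaster spreading produces the larger transient tension excess;\n")
cat("the difference relaxes away once spreading completes.\n")
write.csv(out, "results/04_tension_difference.csv", row.names = FALSE)
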