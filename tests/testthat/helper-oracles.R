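# Independent oracles used across test files. These deliberately avoid the
# package's solution paths: the steady-state oracle scans a 2-D grid, the
# cubic oracle bisects, the derivative oracle uses finite differences.

# Brute-force pump-and-leak steady state: minimise the squared residuals of
# electroneutrality and osmotic balance over a (Vw, Vm) grid, with internal
# concentrations from the zero-flux conditions. Successive grid refinement.
bruteforce_steady_state <- function(p, n_grid = 61, n_refine = 8) {
  vt <- osmovol:::THERMAL_VOLTAGE_MV
  Pi_ext <- p$cNa_ext + p$cK_ext + p$cCl_ext
  resid2 <- function(Vw, Vm) {
    cNa <- p$cNa_ext * exp(-(Vm + 3 * p$pump_rate / p$gNa) / vt)
    cK <- p$cK_ext * exp(-(Vm - 2 * p$pump_rate / p$gK) / vt)
    cCl <- p$cCl_ext * exp(Vm / vt)
    en <- cNa + cK - cCl + p$zX * p$nX / Vw
    os <- cNa + cK + cCl + (p$nX + p$nY) / Vw - Pi_ext
    en^2 + os^2
  }
  Vw_lo <- 10; Vw_hi <- 50 * p$V_iso
  Vm_lo <- -150; Vm_hi <- 20
  for (r in seq_len(n_refine)) {
    Vw_g <- seq(Vw_lo, Vw_hi, length.out = n_grid)
    Vm_g <- seq(Vm_lo, Vm_hi, length.out = n_grid)
    rr <- outer(Vw_g, Vm_g, resid2)
    ij <- arrayInd(which.min(rr), dim(rr))
    i <- ij[1]; j <- ij[2]
    dVw <- Vw_g[2] - Vw_g[1]; dVm <- Vm_g[2] - Vm_g[1]
    Vw_lo <- max(10, Vw_g[i] - 2 * dVw); Vw_hi <- Vw_g[i] + 2 * dVw
    Vm_lo <- Vm_g[j] - 2 * dVm; Vm_hi <- Vm_g[j] + 2 * dVm
  }
  list(Vw = Vw_g[i], Vm = Vm_g[j],
       V = Vw_g[i] + p$excluded_fraction * p$V_iso)
}

# Bisection root of the cap-height cubic h^3 + 3 a^2 h - 6 V / pi = 0.
bisect_cap_height <- function(V, Ac, tol = 1e-12) {
  a2 <- Ac / pi
  f <- function(h) h^3 + 3 * a2 * h - 6 * V / pi
  lo <- 0; hi <- (6 * V / pi)^(1 / 3)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Central finite differences of Atot(V, Ac) via the package's shape
# constructor only (not its analytic derivatives).
fd_area_derivatives <- function(V, Ac, h_rel = 1e-6) {
  atot <- function(V, Ac) cap_from_volume_contact(V, Ac)$Atot
  dV <- V * h_rel
  dAc <- Ac * h_rel
  dAtot_dV <- (atot(V + dV, Ac) - atot(V - dV, Ac)) / (2 * dV)
  dAtot_dAc <- (atot(V, Ac + dAc) - atot(V, Ac - dAc)) / (2 * dAc)
  A0 <- atot(V, Ac)
  list(f1 = dAtot_dV / A0, f2 = dAtot_dAc / A0)
}

# Noise-free trajectory table from a forward spreading simulation, sampled
# at integer minutes.
noiseless_traj <- function(xi, tau, ansatz, V_iso = 2000, r_growth = 0.05,
                           duration = 60, dt_sample = 1) {
  mp <- mechano_params(xi = xi, tau = tau, r_growth = r_growth,
                       V_iso = V_iso)
  sim <- simulate_spreading_volume(mp, ansatz, duration = duration, dt = 0.1)
  tt <- seq(0, duration, by = dt_sample)
  data.frame(
    cell_id = "synth",
    time_min = tt,
    volume_um3 = stats::approx(sim$time_min, sim$V, tt)$y,
    area_um2 = ansatz_area(ansatz, tt))
}
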