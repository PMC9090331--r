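test_that("default steady state reproduces the calibrated interior", {
  p <- default_ion_params()
  ss <- solve_steady_state(p)
  expect_equal(ss$cNa, 15, tolerance = 1e-6)
  expect_equal(ss$cK, 120, tolerance = 1e-6)
  expect_equal(ss$cCl, 65, tolerance = 1e-6)
  # 200 mM of ions, 300 mM total with the impermeant osmolytes
  expect_equal(ss$cNa + ss$cK + ss$cCl, 200, tolerance = 1e-6)
  expect_equal(ss$cNa + ss$cK + ss$cCl + (p$nX + p$nY) / ss$Vw, 300,
               tolerance = 1e-6)
  expect_equal(ss$V, 2000, tolerance = 1e-8)
  # electroneutrality including the charged impermeants
  expect_lt(abs(ss$cNa + ss$cK - ss$cCl + p$zX * p$nX / ss$Vw), 1e-6)
})

test_that("steady state agrees with the 2-D brute-force grid oracle", {
  set.seed(7)
  n_ok <- 0
  while (n_ok < 20) {
    p <- default_ion_params()
    p$pump_rate <- runif(1, 15, 45)
    p$gNa <- runif(1, 0.7, 2)
    p$gK <- runif(1, 0.7, 2)
    p$nX <- runif(1, 1e5, 1.8e5)
    p$nY <- runif(1, 0, 3e4)
    ss <- tryCatch(solve_steady_state(p), error = function(e) NULL)
    if (is.null(ss)) next   # this draw admits no steady state; redraw
    bf <- bruteforce_steady_state(p)
    expect_lt(abs(bf$V - ss$V) / ss$V, 0.01)
    n_ok <- n_ok + 1
  }
})

test_that("degenerate and divergent parameter sets fail loudly", {
  # no impermeant osmolytes: volume undetermined
  p <- default_ion_params()
  p$nX <- 0; p$nY <- 0
  expect_error(solve_steady_state(p), "undetermined")
  # pump off: the classical divergence, no finite steady volume
  p2 <- default_ion_params()
  p2$pump_rate <- 0
  expect_error(solve_steady_state(p2), "no positive-volume")
})

test_that("parameter validation enforces the physical constraints", {
  expect_error(ion_params(zX = 0.5), "negative")
  expect_error(ion_params(excluded_fraction = 1.2), "excluded_fraction")
  expect_error(ion_params(cNa_ext = 100, cK_ext = 5, cCl_ext = 150),
               "electroneutral")
  expect_error(ion_params(gNa = -1), "non-negative")
})

test_that("Ponder passive volume is the affine water-equilibration law", {
  # isosmotic identity and the published regression line evaluated at 0.6
  expect_equal(ponder_passive_volume(1, 0.67), 1)
  expect_equal(ponder_passive_volume(0.6, 0.67), 0.732)
  # infinite-osmolarity limit leaves the osmotically inactive fraction
  expect_equal(ponder_passive_volume(1e-12, 0.67), 0.33,
               tolerance = 1e-8)
  expect_error(ponder_passive_volume(-1, 0.67), "positive")
  expect_error(ponder_passive_volume(1, 1.5), "active_fraction")
})

test_that("no-shock protocol leaves the volume constant", {
  p <- default_ion_params()
  ss <- solve_steady_state(p)
  prot <- shock_protocol(10, 1, duration = 300, dt = 1)
  tr <- simulate_osmotic_shock(p, ss, prot)
  expect_lt(max(abs(tr$V - ss$V)) / ss$V, 1e-3)
})

test_that("passive shocks (k_reg = 0) converge to the Ponder volume", {
  p <- default_ion_params(k_reg = 0)
  ss <- solve_steady_state(p)
  R <- 1 - p$excluded_fraction
  for (ratio in c(0.4, 0.6, 1, 1.5, 2)) {
    prot <- shock_protocol(1, ratio, duration = 900, dt = 1)
    tr <- simulate_osmotic_shock(p, ss, prot)
    expect_equal(utils::tail(tr$V, 1) / ss$V,
                 ponder_passive_volume(ratio, R),
                 tolerance = 5e-3)
  }
})

test_that("ion amounts follow only the stated regulatory flux", {
  p <- default_ion_params(k_reg = 0)
  ss <- solve_steady_state(p)
  prot <- shock_protocol(1, 1.5, duration = 600, dt = 1)
  tr <- simulate_osmotic_shock(p, ss, prot)
  # passive response: ion content exactly conserved
  for (col in c("nNa", "nK", "nCl")) {
    expect_lt(max(abs(tr[[col]] - tr[[col]][1])) / tr[[col]][1], 1e-9)
  }
  # with regulation, Na is untouched and K/Cl move as electroneutral pairs
  p2 <- default_ion_params()
  tr2 <- simulate_osmotic_shock(p2, solve_steady_state(p2), prot)
  expect_lt(max(abs(tr2$nNa - tr2$nNa[1])) / tr2$nNa[1], 1e-9)
  expect_equal(tr2$nK - tr2$nK[1], tr2$nCl - tr2$nCl[1], tolerance = 1e-6)
})

test_that("regulated shocks adapt back toward the resting volume, faster for larger shocks", {
  p <- default_ion_params()
  ss <- solve_steady_state(p)
  rates <- sapply(c(1.3, 1.6, 2), function(ratio) {
    prot <- shock_protocol(1, ratio, duration = 1200, dt = 1)
    tr <- simulate_osmotic_shock(p, ss, prot)
    tr$time_s <- tr$time_s - 1
    dev_peak <- max(tr$V) - ss$V
    dev_end <- abs(utils::tail(tr$V, 1) - ss$V)
    expect_lt(dev_end, dev_peak)   # |V - V_iso| decays after the extremum
    adaptation_rate(tr)
  })
  expect_true(all(rates < 0))                       # recovery is downward
  expect_true(all(diff(abs(rates)) > 0))            # larger shock, larger flux
})

test_that("over-coarse shock sampling is rejected, not integrated blindly", {
  p <- default_ion_params()
  ss <- solve_steady_state(p)
  prot <- shock_protocol(10, 2, duration = 3000, dt = 600)
  expect_error(simulate_osmotic_shock(p, ss, prot), "too.*coarse|coarse")
})

test_that("permeability is recovered from the initial passive slope", {
  p <- default_ion_params(k_reg = 0)
  ss <- solve_steady_state(p)
  # hypo shock: swelling probes Lp_in
  prot <- shock_protocol(1, 1.5, duration = 120, dt = 1)
  tr <- simulate_osmotic_shock(p, ss, prot,
                               times_s = seq(0, 120, by = 0.05))
  tr$time_s <- tr$time_s - 1
  dPi <- p$RT * (300 - 300 / 1.5)
  Lp_hat <- estimate_permeability(tr, ss$A, dPi, region_s = c(0, 0.2))
  expect_equal(Lp_hat, p$Lp_in, tolerance = 0.02)
  # hyper shock probes the (smaller) Lp_out; ordering must be preserved
  prot2 <- shock_protocol(1, 0.7, duration = 120, dt = 1)
  tr2 <- simulate_osmotic_shock(p, ss, prot2,
                                times_s = seq(0, 120, by = 0.05))
  tr2$time_s <- tr2$time_s - 1
  Lp_out_hat <- estimate_permeability(tr2, ss$A, p$RT * (300 / 0.7 - 300),
                                      region_s = c(0, 0.2))
  expect_equal(Lp_out_hat, p$Lp_out, tolerance = 0.02)
  expect_lt(Lp_out_hat, Lp_hat)
  # degenerate inputs
  flat <- data.frame(time_s = 0:10, V = rep(2000, 11))
  expect_equal(estimate_permeability(flat, 800, 1e4, region_s = c(0, 10)), 0)
  expect_error(estimate_permeability(tr, 0, dPi), "area")
  expect_error(estimate_permeability(tr, ss$A, 0), "delta_Pi")
})

test_that("adaptation rate is the 5-min post-extremum slope", {
  # exact linear recovery after an extremum at t = 60 s
  tt <- seq(0, 600, by = 10)
  V <- ifelse(tt <= 60, 1000 + (tt / 60) * 50, 1050 + 4 * (tt - 60) / 60)
  tr <- data.frame(time_s = tt, V = V)
  expect_equal(adaptation_rate(tr), 4, tolerance = 1e-10)
  # constant after extremum
  V2 <- ifelse(tt <= 60, 1000 + (tt / 60) * 50, 1050)
  expect_equal(adaptation_rate(data.frame(time_s = tt, V = V2)), 0,
               tolerance = 1e-10)
  # flat trace: no extremum
  expect_error(adaptation_rate(data.frame(time_s = tt, V = rep(1000, length(tt)))),
               "no extremum")
})

test_that("scalar pressure relations match their definitions", {
  expect_equal(bulk_modulus(2000, 1e4, 200), 1e5)
  expect_error(bulk_modulus(2000, 1e4, 0), "delta_V")
  # small-shock limit: B ~ Pi_total / active_fraction
  R <- 0.67; Pi_iso <- 300 * 2577
  ratio <- 1.001   # small hypo shock
  dV <- 2000 * (ponder_passive_volume(ratio, R) - 1)
  dP <- Pi_iso * (1 - 1 / ratio)
  expect_equal(bulk_modulus(2000, dP, dV), Pi_iso / R, tolerance = 2e-3)

  expect_equal(laplace_pressure(1, 10), 200)
  expect_equal(laplace_pressure(0, 5), 0)
  expect_equal(laplace_pressure(2, 10), laplace_pressure(1, 5))
  expect_error(laplace_pressure(1, 0), "radius")

  tp <- trapped_pressure_change(1e5, 0.10)
  expect_equal(tp$linearized, 1e4)
  expect_equal(tp$exact, 1e5 * 0.1 / 0.9)
  expect_equal(trapped_pressure_change(1e5, 0)$linearized, 0)

  expect_equal(contractility_volume_bound(10, 100, 1e5), 0.01)
  expect_equal(contractility_volume_bound(1, 100, 1e5), 1e-3)
  expect_equal(contractility_volume_bound(0, 100, 1e5), 0)
  expect_error(contractility_volume_bound(1, 100, 0), "Pi_total")
})
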