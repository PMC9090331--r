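test_that("alpha sign follows which conductance is tension-activated", {
  expect_equal(mechanosensitivity_alpha(default_ion_params()), 0,
               tolerance = 1e-8)                       # no sensitivity
  expect_lt(mechanosensitivity_alpha(default_ion_params(betaK = 1)), 0)
  expect_gt(mechanosensitivity_alpha(default_ion_params(betaNa = 1)), 0)
})

test_that("alpha matches an independent two-point steady-state recomputation", {
  set.seed(5)
  for (i in 1:5) {
    p <- default_ion_params(betaNa = runif(1, 0, 2), betaK = runif(1, 0, 2),
                            betaCl = runif(1, 0, 1))
    a <- mechanosensitivity_alpha(p)
    # independent: one-sided secant at a different, coarser step
    eps <- 5e-3
    perturb <- function(e) {
      ps <- p
      ps$gNa <- p$gNa * (1 + p$betaNa * e)
      ps$gK <- p$gK * (1 + p$betaK * e)
      ps$gCl <- p$gCl * (1 + p$betaCl * e)
      solve_steady_state(ps)$V
    }
    a2 <- (log(perturb(eps)) - log(perturb(-eps))) / (2 * eps)
    expect_lt(abs(a - a2), 1e-3)
  }
})

test_that("Maxwell tension response matches the linear-ODE closed forms", {
  p <- mechano_params(xi = NULL, alpha = -0.05, k = 0.01, gamma_iso = 0.3,
                      Atot_iso = 800, tau = 8, V_iso = 2000)
  # constant area growth rate s: plateau (k s tau / gamma_iso)(1 - e^(-t/tau))
  tt <- seq(0, 80, by = 0.01)
  s <- 2                                  # um^2/min
  lnA <- log(800 + s * tt)
  x <- tension_response(tt, lnA, p)
  pred <- p$k * s * p$tau / p$gamma_iso * (1 - exp(-tt / p$tau))
  expect_equal(x[tt >= 10 * p$tau][1], p$k * s * p$tau / p$gamma_iso,
               tolerance = 1e-3)
  expect_lt(max(abs(x - pred)), 2e-3 * max(abs(pred)))
  # static area: tension stays zero
  x0 <- tension_response(tt, rep(log(800), length(tt)), p)
  expect_equal(max(abs(x0)), 0)
  # step increase: jump k dA / gamma_iso then exp(-t/tau) relaxation
  lnA_step <- log(c(rep(800, 1000), rep(820, length(tt) - 1000)))
  xs <- tension_response(tt, lnA_step, p)
  jump <- p$k * 20 / p$gamma_iso
  i_step <- 1001
  expect_equal(max(xs), jump, tolerance = 0.02)
  t_rel <- tt[-(1:i_step)] - tt[i_step]
  expect_equal(xs[-(1:i_step)], jump * exp(-t_rel / p$tau),
               tolerance = 0.02)
})

test_that("spreading simulation limits: decoupled growth, elastic, viscous", {
  anz <- spreading_ansatz(50, 1200, 15)
  # xi = 0: pure growth, exact
  m0 <- mechano_params(xi = 0, tau = 15, r_growth = 0.05, V_iso = 2000)
  s0 <- simulate_spreading_volume(m0, anz, 60, 0.1)
  expect_equal(s0$V, 2000 * (1 + 0.05 / 60 * s0$time_min), tolerance = 1e-10)
  # elastic limit tau >> tau_a, no growth: dV/V = -xi ln(Atot/Atot0)
  mE <- mechano_params(xi = 0.3, tau = 1000 * 15, r_growth = 0, V_iso = 2000)
  sE <- simulate_spreading_volume(mE, anz, 60, 0.05)
  pred <- -0.3 * log(sE$Atot / sE$Atot[1])
  expect_equal(utils::tail(sE$u, 1), utils::tail(pred, 1), tolerance = 0.01)
  # viscous limit tau -> 0: slow deformation at constant volume
  mV <- mechano_params(xi = 0.3, tau = 0.01, r_growth = 0, V_iso = 2000)
  sV <- simulate_spreading_volume(mV, anz, 60, 0.05)
  expect_lt(max(abs(sV$u)), 1e-3)
})

test_that("peak volume loss scales with spreading speed over a decade", {
  # linear rate-to-loss conversion holds in the Maxwell-filtered regime
  # tau_a >> tau, where the tension (and hence the loss) tracks the
  # instantaneous area growth rate
  tau_as <- c(15, 30, 75, 150)
  losses <- sapply(tau_as, function(tau_a) {
    anz <- spreading_ansatz(50, 1200, tau_a)
    m <- mechano_params(xi = 0.05, tau = 3, r_growth = 0, V_iso = 2000)
    s <- simulate_spreading_volume(m, anz, 6 * tau_a, 0.05)
    max(-s$u)
  })
  expect_true(all(diff(losses) < 0))  # slower spreading, less loss
  # proportionality to 1/tau_a within 20 % across the decade
  ratio <- losses * tau_as
  expect_lt(max(ratio) / min(ratio), 1.2)
})

test_that("halving the integration step leaves the trajectory unchanged", {
  anz <- spreading_ansatz(50, 1200, 10)
  m <- mechano_params(xi = 0.3, tau = 15, r_growth = 0.05, V_iso = 2000)
  s1 <- simulate_spreading_volume(m, anz, 40, 0.1)
  s2 <- simulate_spreading_volume(m, anz, 40, 0.05)
  v1 <- s1$V[s1$time_min %in% seq(0, 40, 5)]
  v2 <- s2$V[s2$time_min %in% seq(0, 40, 5)]
  expect_equal(v1, v2, tolerance = 1e-5)
})

test_that("quasi-static consistency: volume tracks alpha times tension", {
  # tau_eff d/dt << 1: slow spreading, short tau
  anz <- spreading_ansatz(100, 600, 120)
  p <- mechano_params(xi = NULL, alpha = -0.1, k = 0.3 * 0.5 / (800 * 0.1),
                      gamma_iso = 0.5, Atot_iso = 800, tau = 2,
                      r_growth = 0, V_iso = 2000)
  expect_gt(p$xi, 0)          # sign structure: alpha < 0 <=> xi > 0
  s <- simulate_spreading_volume(p, anz, 240, 0.05)
  late <- s$time_min > 20
  expect_equal(s$u[late], p$alpha * s$tension[late], tolerance = 0.02)
})

test_that("uncoupled cells carry the larger transient tension", {
  anz <- spreading_ansatz(50, 1200, 8)
  p <- mechano_params(xi = NULL, alpha = -0.01, k = 100 * 0.4 / 800,
                      gamma_iso = 0.4, Atot_iso = 800, tau = 15,
                      r_growth = 0.05, V_iso = 2000)
  td <- tension_difference_without_coupling(p, anz, duration = 120, dt = 0.1)
  # while the contact area is still growing the uncoupled cell is tenser;
  # once the coupled cell's volume dip starts recovering (around 2 tau_a)
  # its extra area growth can transiently reverse the tiny residual
  spreading <- td$time_min <= 2 * 8
  expect_true(all(td$diff[spreading] >= -1e-10))
  i_peak <- which.max(td$diff)
  expect_lt(td$time_min[i_peak], 2 * 8)       # peaks during spreading
  expect_lt(abs(utils::tail(td$diff, 1)), 0.1 * max(td$diff))  # relaxes away
  # faster spreading gives a larger peak difference
  anz_fast <- spreading_ansatz(50, 1200, 3)
  td_fast <- tension_difference_without_coupling(p, anz_fast, 120, 0.1)
  expect_gt(max(td_fast$diff), max(td$diff))
  # alpha = 0 input: identically zero difference
  p0 <- mechano_params(xi = 0, tau = 15, k = 0.05, gamma_iso = 0.4,
                       alpha = 0, Atot_iso = 800, r_growth = 0.05,
                       V_iso = 2000)
  td0 <- tension_difference_without_coupling(p0, anz, 60, 0.1)
  expect_equal(max(abs(td0$diff)), 0)
})

test_that("migration CV transfer function: limits and monotonicity", {
  mp <- migration_params(forcing_amplitude = 0.1, mesh_spacing = 50,
                         xi = 1, tau = 30, tau_eff = 40)
  expect_equal(migration_cv_model(0, mp), 0)
  # high-speed saturation
  expect_equal(migration_cv_model(1e6, mp),
               mp$xi * mp$forcing_amplitude * mp$tau / (sqrt(2) * mp$tau_eff),
               tolerance = 1e-6)
  v <- seq(0, 3, by = 0.1)
  expect_true(all(diff(migration_cv_model(v, mp)) > 0))
})

test_that("migration CV fit recovers the lumped parameters", {
  mp <- migration_params(forcing_amplitude = 0.1, mesh_spacing = 50,
                         xi = 1, tau = 30, tau_eff = 40)
  set.seed(2)
  speeds <- runif(40, 0.1, 2)
  cv_true <- migration_cv_model(speeds, mp)
  cvs <- cv_true * (1 + rnorm(40, 0, 0.05))
  fit <- fit_migration_cv(speeds, cvs, mesh_spacing = 50)
  expect_true(fit$converged)
  amp_true <- mp$xi * mp$forcing_amplitude * mp$tau
  expect_equal(fit$amp, amp_true, tolerance = 0.15)
  expect_equal(fit$tau_eff, mp$tau_eff, tolerance = 0.15)
  # degenerate inputs
  expect_equal(fit_migration_cv(speeds, rep(0, 40))$amp, 0)
  expect_error(fit_migration_cv(rep(1, 10), rep(0.01, 10)), "degenerate")
})
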