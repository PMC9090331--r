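test_that("onset alignment re-zeroes at the first detectable area", {
  traj <- data.frame(time_min = 0:4,
                     area_um2 = c(0, 0, 40, 200, 600),
                     volume_um3 = 2000 + 0:4)
  al <- align_spreading_onset(traj)
  expect_equal(al$time_min, 0:2)
  expect_equal(al$area_um2[1], 40)
  expect_equal(al$volume_um3[1], 2002)   # pre-onset samples dropped
  # first detectable area above threshold: exclusion, not silent pass
  traj2 <- data.frame(time_min = 0:3, area_um2 = c(0, 150, 300, 500))
  expect_error(align_spreading_onset(traj2), "excluded",
               class = "osmovol_onset_error")
  # never-detected cell
  traj3 <- data.frame(time_min = 0:3, area_um2 = c(0, 0, 0, 0))
  expect_error(align_spreading_onset(traj3), class = "osmovol_onset_error")
})

test_that("area ansatz fit recovers noiseless parameters and flags bound hits", {
  tt <- 0:60
  anz <- spreading_ansatz(50, 1200, 15)
  traj <- data.frame(time_min = tt, area_um2 = ansatz_area(anz, tt))
  fit <- fit_area_ansatz(traj)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["A0"]), 1200, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["tau_a"]), 15, tolerance = 1e-3)
  expect_false(any(fit$bounds_hit))
  # linear-in-time area: tau_a runs into its bound, flagged
  lin <- data.frame(time_min = tt, area_um2 = 50 + 3 * tt)
  fit_lin <- fit_area_ansatz(lin)
  expect_true(fit_lin$bounds_hit["tau_a"] || fit_lin$bounds_hit["A0"])
  expect_error(fit_area_ansatz(traj[1:4, ]), ">= 6")
})

test_that("volume fit round-trips noiseless forward simulations", {
  anz <- spreading_ansatz(50, 1200, 15)
  traj <- noiseless_traj(xi = 0.5, tau = 20, anz)
  fit <- fit_volume_params(traj, anz, r_growth = 0.05, dt = 0.1)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["xi"]), 0.5, tolerance = 0.01)
  expect_equal(unname(fit$estimates["tau"]), 20, tolerance = 0.01)
  # growth-only trace fits to xi ~ 0 (valid result, not an error)
  traj0 <- noiseless_traj(xi = 0, tau = 20, anz)
  fit0 <- fit_volume_params(traj0, anz, r_growth = 0.05, dt = 0.1)
  expect_lt(unname(fit0$estimates["xi"]), 0.01)
})

test_that("initial fluxes are OLS slopes over the first window", {
  tt <- 0:15
  traj <- data.frame(time_min = tt,
                     volume_um3 = 2000 - 5 * tt,
                     area_um2 = 50 + 20 * tt)
  fx <- initial_fluxes(traj, window_min = 10)
  expect_equal(fx$dVdt, -5, tolerance = 1e-10)
  expect_equal(fx$dAdt, 20, tolerance = 1e-10)
  # ansatz slope matches the analytic mean-derivative scale
  anz <- spreading_ansatz(50, 1200, 15)
  traj2 <- data.frame(time_min = tt, area_um2 = ansatz_area(anz, tt),
                      volume_um3 = NA_real_)
  fx2 <- initial_fluxes(traj2, window_min = 10)
  # OLS slope of a saturating curve lies between the endpoint secant and
  # the initial derivative
  secant <- (ansatz_area(anz, 10) - ansatz_area(anz, 0)) / 10
  expect_gt(fx2$dAdt, 0.8 * secant)
  expect_lt(fx2$dAdt, ansatz_area_rate(anz, 0))
  expect_true(is.na(fx2$dVdt))   # too few volume points, flagged missing
})

test_that("flat noisy volumes give slope estimates centred on zero", {
  set.seed(9)
  slopes <- replicate(200, {
    traj <- data.frame(time_min = 0:10,
                       volume_um3 = 2000 * rlnorm(11, 0, 0.01),
                       area_um2 = NA_real_)
    initial_fluxes(traj)$dVdt
  })
  expect_lt(abs(mean(slopes)), 2 * stats::sd(slopes) / sqrt(200))
})

test_that("speed terciles are balanced, deterministic, tie-stable", {
  # 127 cells split 42/43/42
  set.seed(4)
  g <- classify_by_speed(runif(127))
  expect_equal(as.integer(table(g)), c(42L, 43L, 42L))
  # 9 distinct speeds: 3/3/3, permutation invariant
  x <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  g9 <- classify_by_speed(x)
  expect_equal(as.integer(table(g9)), c(3L, 3L, 3L))
  perm <- sample(9)
  expect_equal(classify_by_speed(x[perm]), g9[perm])
  expect_equal(g9[x <= 3], factor(rep("slow", 3),
                                  levels = c("slow", "moderate", "fast")))
  # boundary ties go to the lower group
  xt <- c(1, 2, 2, 2, 5, 6)
  gt <- classify_by_speed(xt)
  expect_true(all(gt[xt == 2] == "slow"))
  # all equal: degenerate single group, warned
  expect_warning(classify_by_speed(rep(1, 6)), "equal")
})

test_that("flux regression returns OLS slope, intercept, R^2", {
  # perfectly collinear
  dA <- 1:10
  r <- flux_regression(dA, -0.31 * dA - 0.71)
  expect_equal(r$slope, -0.31)
  expect_equal(r$intercept, -0.71)
  expect_equal(r$r_squared, 1)
  # zero-slope data
  set.seed(12)
  r0 <- flux_regression(rnorm(100), rnorm(100))
  expect_lt(abs(r0$slope), 0.3)
  expect_lt(r0$r_squared, 0.05)
})

test_that("regression estimators are unbiased on synthetic linear data", {
  set.seed(21)
  slopes <- replicate(100, {
    x <- runif(200, 0, 20)
    y <- -0.31 * x - 0.71 + rnorm(200, 0, 2)
    flux_regression(x, y)$slope
  })
  expect_lt(abs(mean(slopes) - (-0.31)), 0.02 * 0.31)
})

test_that("Ponder regression recovers the active fraction", {
  ratios <- c(0.4, 0.6, 0.82, 1, 1.11, 2)
  v <- ponder_passive_volume(ratios, 0.67)
  r <- ponder_regression(ratios, v)
  expect_equal(r$slope, 0.67, tolerance = 1e-10)
  expect_equal(r$intercept, 0.33, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_equal(r$sum_check$estimate, 1, tolerance = 1e-10)
  expect_true(r$sum_check$consistent)
  expect_error(ponder_regression(rep(1, 5), rnorm(5)), "distinct")
})

test_that("windowed flux CV matches the analytic windowing oracle", {
  # constant slope: zero fluctuation
  traj <- data.frame(time_min = 0:120, volume_um3 = 2000 + 2 * (0:120))
  expect_equal(windowed_flux_cv(traj), 0, tolerance = 1e-10)
  # sinusoid: OLS slope of A sin(w t + phi) over window T has amplitude
  # 3 A w (sin x - x cos x) / x^3 with x = w T / 2; std over phase is /sqrt(2)
  Vbar <- 2000; A_rel <- 0.02; period <- 60; Tw <- 10
  w <- 2 * pi / period
  x <- w * Tw / 2
  tt <- seq(0, 600, by = 0.5)
  n_windows <- 60
  sl_amp <- 3 * (A_rel * Vbar) * w * (sin(x) - x * cos(x)) / x^3
  cv_pred <- (sl_amp / sqrt(2)) / (Vbar / Tw)
  traj2 <- data.frame(time_min = tt,
                      volume_um3 = Vbar * (1 + A_rel * sin(w * tt)))
  expect_equal(windowed_flux_cv(traj2, window_min = Tw), cv_pred,
               tolerance = 0.05)
  expect_error(windowed_flux_cv(traj2[tt <= 15, ]), "3 usable windows")
})

test_that("full pipeline recovers cohort parameters from noisy data", {
  cfg <- condition_preset("control", n_cells = 12, seed = 404,
                          duration = 60)
  coh <- generate_spreading_cohort(cfg)
  res <- fit_cohort(coh$trajectories, fit_volume = FALSE)
  cells <- merge(res$cells, coh$truth, by = "cell_id",
                 suffixes = c("", "_true"))
  expect_equal(nrow(cells), 12)
  expect_lt(stats::median(abs(cells$tau_a - cells$tau_a_true) /
                            cells$tau_a_true), 0.10)
  expect_lt(stats::median(abs(cells$A0 - cells$A0_true) / cells$A0_true),
            0.10)
})
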