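#' Align a single-cell trajectory on spreading onset
#'
#' Spreading onset is the first sample whose contact area is detectable
#' (> 0) and does not exceed `area_threshold`; time is re-zeroed there and
#' earlier samples are dropped. If the first detectable area already
#' exceeds the threshold the onset was missed and the cell is excluded
#' (a classed error of class `osmovol_onset_error`, so cohort drivers can
#' catch and count exclusions rather than silently passing the cell on).
#'
#' @param traj Data frame for one cell with columns `time_min`,
#'   `area_um2` and optionally `volume_um3`.
#' @param area_threshold Largest contact area (um^2) accepted as onset.
#' @return The aligned trajectory (same columns, re-zeroed `time_min`).
#' @export
align_spreading_onset <- function(traj, area_threshold = 100) {
  if (!"area_um2" %in% names(traj)) {
    stop("align_spreading_onset: trajectory has no area_um2 column",
         call. = FALSE)
  }
  detected <- which(!is.na(traj$area_um2) & traj$area_um2 > 0)
  if (length(detected) == 0) {
    stop(structure(class = c("osmovol_onset_error", "error", "condition"),
                   list(message = "no detectable contact area; cell excluded",
                        call = NULL)))
  }
  i0 <- detected[1]
  if (traj$area_um2[i0] > area_threshold) {
    stop(structure(class = c("osmovol_onset_error", "error", "condition"),
                   list(message = paste0(
                     "first detectable area ", signif(traj$area_um2[i0], 4),
                     " um^2 exceeds onset threshold ", area_threshold,
                     " um^2; cell excluded"), call = NULL)))
  }
  out <- traj[seq(i0, nrow(traj)), , drop = FALSE]
  out$time_min <- out$time_min - out$time_min[1]
  rownames(out) <- NULL
  out
}

new_fit_result <- function(estimates, rss, n, converged, bounds_hit) {
  structure(list(estimates = estimates, rss = rss, n = n,
                 converged = converged, bounds_hit = bounds_hit),
            class = "fit_result")
}

#' Fit the exponential-saturation spreading ansatz to a contact-area trace
#'
#' Nonlinear least squares of Ac(t) = A_init + (A0 - A_init)
#' (1 - exp(-t/tau_a)) on an onset-aligned trajectory. The onset area
#' A_init is fixed to the first observed area, leaving two free parameters
#' (A0, tau_a), fitted within bounds A0 in (A_init, 1e4] um^2 and tau_a in
#' [0.5, 500] min. Hitting a bound (e.g. tau_a pinned high for a trace
#' that is still linear when the record ends) is flagged, not hidden.
#'
#' @param traj Aligned trajectory with >= 6 non-missing area samples.
#' @param tau_a_bounds,A0_upper Fit bounds.
#' @return A `fit_result` with estimates `A_init`, `A0`, `tau_a`.
#' @export
fit_area_ansatz <- function(traj, tau_a_bounds = c(0.5, 500),
                            A0_upper = 1e4) {
  ok <- !is.na(traj$area_um2)
  tt <- traj$time_min[ok]; aa <- traj$area_um2[ok]
  if (length(tt) < 6) {
    stop("fit_area_ansatz: need >= 6 area samples", call. = FALSE)
  }
  A_init <- aa[1]
  df <- data.frame(t = tt, a = aa)
  start <- list(A0 = max(max(aa), A_init + 10),
                tau_a = max(tau_a_bounds[1],
                            min(tau_a_bounds[2], max(tt) / 3)))
  fit <- try(minpack.lm::nlsLM(
    a ~ A_init + (A0 - A_init) * (1 - exp(-t / tau_a)),
    data = df, start = start,
    lower = c(A0 = A_init + 1e-6, tau_a = tau_a_bounds[1]),
    upper = c(A0 = A0_upper, tau_a = tau_a_bounds[2]),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(new_fit_result(c(A_init = A_init, A0 = NA, tau_a = NA),
                          NA_real_, length(tt), FALSE, c(FALSE, FALSE)))
  }
  est <- stats::coef(fit)
  tol <- 1e-6
  bounds_hit <- c(
    A0 = est["A0"] >= A0_upper * (1 - tol),
    tau_a = est["tau_a"] <= tau_a_bounds[1] * (1 + tol) ||
      est["tau_a"] >= tau_a_bounds[2] * (1 - tol))
  new_fit_result(c(A_init = A_init, A0 = unname(est["A0"]),
                   tau_a = unname(est["tau_a"])),
                 sum(stats::resid(fit)^2), length(tt),
                 isTRUE(fit$convInfo$isConv), bounds_hit)
}

#' Fit the mechano-osmotic coupling parameters to a volume trace
#'
#' Least-squares fit of the two model parameters (xi, tau) on normalised
#' volume against the forward simulation [simulate_spreading_volume()],
#' with the spreading ansatz, growth rate and V_iso held fixed. V_iso is
#' the mean of the first three volume samples (the normalisation
#' convention used throughout). The objective is minimised from four fixed
#' starting points (multi-start) with L-BFGS-B within xi in [0, 10] and
#' tau in [0.5, 200] min; a flat trace fitting to xi = 0 at the bound is a
#' valid result, not an error.
#'
#' @param traj Aligned trajectory with volume samples.
#' @param ansatz A fitted [spreading_ansatz()].
#' @param r_growth Growth rate, fraction per hour (fixed).
#' @param dt Forward-simulation step (min).
#' @param xi_bounds,tau_bounds Fit bounds.
#' @return A `fit_result` with estimates `xi`, `tau` and fields `V_iso`.
#' @export
fit_volume_params <- function(traj, ansatz, r_growth = 0.05, dt = 0.2,
                              xi_bounds = c(0, 10),
                              tau_bounds = c(0.5, 200)) {
  ok <- !is.na(traj$volume_um3)
  tt <- traj$time_min[ok]; vv <- traj$volume_um3[ok]
  if (length(tt) < 4) {
    stop("fit_volume_params: need >= 4 volume samples", call. = FALSE)
  }
  n3 <- seq_len(min(3, length(vv)))
  V_iso <- mean(vv[n3])
  v_norm <- vv / V_iso
  duration <- max(tt)
  # both data and model are normalised by their own first-3-sample mean, so
  # the objective is invariant to the per-cell measurement scale offset
  model_at <- function(xi, tau) {
    p <- mechano_params(xi = xi, tau = tau, r_growth = r_growth,
                        V_iso = V_iso)
    sim <- simulate_spreading_volume(p, ansatz, duration = duration,
                                     dt = dt, normalized = TRUE)
    m <- stats::approx(sim$time_min, sim$V_norm, xout = tt, rule = 2)$y
    m / mean(m[n3])
  }
  obj <- function(par) sum((model_at(par[1], par[2]) - v_norm)^2)
  starts <- rbind(c(0.1, 5), c(0.5, 20), c(2, 50), c(0.05, 100))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- try(stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                            lower = c(xi_bounds[1], tau_bounds[1]),
                            upper = c(xi_bounds[2], tau_bounds[2]),
                            control = list(factr = 1e9)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    out <- new_fit_result(c(xi = NA, tau = NA), NA_real_, length(tt),
                          FALSE, c(FALSE, FALSE))
    out$V_iso <- V_iso
    return(out)
  }
  tol <- 1e-6
  bounds_hit <- c(
    xi = best$par[1] >= xi_bounds[2] * (1 - tol),
    tau = best$par[2] <= tau_bounds[1] * (1 + tol) ||
      best$par[2] >= tau_bounds[2] * (1 - tol))
  out <- new_fit_result(c(xi = best$par[1], tau = best$par[2]),
                        best$value, length(tt),
                        best$convergence == 0, bounds_hit)
  out$V_iso <- V_iso
  out
}

#' Initial spreading and volume fluxes
#'
#' Ordinary least-squares slopes of contact area and volume over the first
#' `window_min` minutes after spreading onset; the standard initial
#' spreading speed dA/dt and volume flux dV/dt.
#'
#' @param traj Aligned trajectory.
#' @param window_min Window length (min), default 10.
#' @return A list of class `flux_estimate` with `dAdt` (um^2/min), `dVdt`
#'   (um^3/min; either may be NA with its flag), `window`, `n_area`,
#'   `n_volume`.
#' @export
initial_fluxes <- function(traj, window_min = 10) {
  win <- traj[traj$time_min <= window_min, , drop = FALSE]
  slope_of <- function(y) {
    ok <- !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(y[ok] ~ win$time_min[ok]))[2])
  }
  dAdt <- if ("area_um2" %in% names(win)) slope_of(win$area_um2) else NA_real_
  dVdt <- if ("volume_um3" %in% names(win)) slope_of(win$volume_um3) else NA_real_
  structure(list(dAdt = dAdt, dVdt = dVdt,
                 window = c(0, window_min),
                 n_area = sum(!is.na(win$area_um2)),
                 n_volume = sum(!is.na(win$volume_um3))),
            class = "flux_estimate")
}

#' Classify cells into speed terciles
#'
#' Splits cells into slow / moderate / fast groups by terciles of their
#' initial spreading speed dA/dt. Group sizes differ by at most one, the
#' remainder cell going to the middle group (so 127 cells split
#' 42/43/42); exact speed ties across a tercile boundary are assigned to
#' the lower group. Deterministic and invariant under permutation of the
#' input order.
#'
#' @param dAdt Numeric vector of initial spreading speeds.
#' @return Factor with levels `slow`, `moderate`, `fast`, same length and
#'   order as `dAdt` (NA speeds give NA group).
#' @export
classify_by_speed <- function(dAdt) {
  n_all <- length(dAdt)
  ok <- which(!is.na(dAdt))
  n <- length(ok)
  if (n < 3) stop("classify_by_speed: need >= 3 cells with dA/dt",
                  call. = FALSE)
  x <- dAdt[ok]
  if (stats::sd(x) == 0) {
    warning("classify_by_speed: all speeds equal; single degenerate group")
    g <- factor(rep("slow", n_all), levels = c("slow", "moderate", "fast"))
    g[-ok] <- NA
    return(g)
  }
  base <- n %/% 3
  rem <- n %% 3
  sizes <- c(base, base, base)
  if (rem == 1) sizes[2] <- sizes[2] + 1
  if (rem == 2) sizes <- sizes + c(1, 0, 1)
  ord <- order(x, seq_along(x))    # stable order; ties keep input order
  grp_sorted <- rep(c("slow", "moderate", "fast"), times = sizes)
  # ties straddling a boundary go to the lower (slower) group
  xs <- x[ord]
  for (b in c(sizes[1], sizes[1] + sizes[2])) {
    if (b < n) {
      tied <- which(xs == xs[b])
      grp_sorted[tied] <- grp_sorted[tied[1]]
    }
  }
  g_ok <- character(n)
  g_ok[ord] <- grp_sorted
  g <- rep(NA_character_, n_all)
  g[ok] <- g_ok
  factor(g, levels = c("slow", "moderate", "fast"))
}

#' Linear regression of volume flux on spreading speed
#'
#' OLS of per-cell dV/dt against dA/dt, the flux-flux scatter relation of
#' the spreading study.
#'
#' @param dAdt,dVdt Numeric vectors (paired; NA pairs dropped; >= 3 left).
#' @return A list of class `regression_result` with `slope` (um^3/um^2),
#'   `intercept` (um^3/min), their standard errors, `r_squared` and `n`.
#' @export
flux_regression <- function(dAdt, dVdt) {
  ok <- !is.na(dAdt) & !is.na(dVdt)
  if (sum(ok) < 3) {
    stop("flux_regression: need >= 3 cells with both fluxes", call. = FALSE)
  }
  fit <- stats::lm(dVdt[ok] ~ dAdt[ok])
  # noiseless synthetic inputs legitimately produce perfect fits
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 intercept_se = sm$coefficients[1, 2],
                 r_squared = sm$r.squared,
                 n = sum(ok)),
            class = "regression_result")
}

#' Ponder regression of passive post-shock volume on osmolarity ratio
#'
#' OLS of the extremal normalised volume V/V_iso on Piso/P across shock
#' magnitudes. The slope estimates the osmotically active volume fraction
#' R, the intercept the inactive fraction 1 - R; for a purely passive
#' response slope + intercept = 1, and the fit reports whether that
#' identity holds within the 95 % confidence interval of the sum.
#'
#' @param ratios Piso/P values (>= 3 distinct).
#' @param v_norm Matching normalised volumes.
#' @return A `regression_result` with additionally `sum_check` (list:
#'   `estimate`, `se`, `consistent`).
#' @export
ponder_regression <- function(ratios, v_norm) {
  ok <- !is.na(ratios) & !is.na(v_norm)
  if (length(unique(ratios[ok])) < 3) {
    stop("ponder_regression: need >= 3 distinct osmolarity ratios",
         call. = FALSE)
  }
  fit <- stats::lm(v_norm[ok] ~ ratios[ok])
  sm <- suppressWarnings(summary(fit))
  cf <- stats::coef(fit)
  vc <- suppressWarnings(stats::vcov(fit))
  sum_est <- unname(cf[1] + cf[2])
  sum_se <- sqrt(vc[1, 1] + vc[2, 2] + 2 * vc[1, 2])
  structure(list(slope = unname(cf[2]),
                 intercept = unname(cf[1]),
                 slope_se = sm$coefficients[2, 2],
                 intercept_se = sm$coefficients[1, 2],
                 r_squared = sm$r.squared,
                 n = sum(ok),
                 sum_check = list(estimate = sum_est, se = sum_se,
                                  consistent = is.na(sum_se) ||
                                    abs(sum_est - 1) <= 1.96 * max(sum_se, 1e-12))),
            class = "regression_result")
}

#' Coefficient of variation of windowed volume flux
#'
#' Splits a volume trace into consecutive windows of `window_min` minutes,
#' takes the OLS slope of volume in each, and summarises the fluctuation
#' of those windowed fluxes. Because the mean flux of a fluctuating track
#' is near zero, the default normalisation divides the standard deviation
#' of the windowed fluxes by the natural volume-flux scale
#' mean(V)/window_min (equivalently: the standard deviation of the
#' relative volume change per window); the plain std/|mean| variant is
#' available via `method = "plain"`.
#'
#' @param traj Data frame with `time_min` and `volume_um3`.
#' @param window_min Window length (min), default 10.
#' @param method `"volume_scale"` (default) or `"plain"`.
#' @return CV (dimensionless).
#' @export
windowed_flux_cv <- function(traj, window_min = 10,
                             method = c("volume_scale", "plain")) {
  method <- match.arg(method)
  ok <- !is.na(traj$volume_um3)
  tt <- traj$time_min[ok]; vv <- traj$volume_um3[ok]
  if (length(tt) == 0) stop("windowed_flux_cv: no volume samples",
                            call. = FALSE)
  idx <- floor((tt - tt[1]) / window_min)
  slopes <- c()
  for (w in unique(idx)) {
    sel <- idx == w
    if (sum(sel) < 3) next
    slopes <- c(slopes, unname(stats::coef(stats::lm(vv[sel] ~ tt[sel]))[2]))
  }
  if (length(slopes) < 3) {
    stop("windowed_flux_cv: trace spans fewer than 3 usable windows",
         call. = FALSE)
  }
  if (method == "plain") {
    stats::sd(slopes) / abs(mean(slopes))
  } else {
    stats::sd(slopes) / (mean(vv) / window_min)
  }
}
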