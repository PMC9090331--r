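#' Mechanosensitivity of steady-state volume to membrane tension
#'
#' If each ion conductance responds to tension as
#' g_i(gamma) = g_i0 (1 + beta_i dgamma/gamma_iso), the steady-state volume
#' becomes tension dependent. The mechanosensitivity
#' alpha = d ln V / d(dgamma/gamma_iso) is evaluated by central finite
#' differences of [solve_steady_state()] at perturbed conductances, with a
#' Richardson step-halving check on the derivative.
#'
#' The sign follows the transport physics: a tension-activated potassium
#' leak (betaK > 0) loses cell potassium and shrinks the cell (alpha < 0);
#' a tension-activated sodium leak (betaNa > 0) lets sodium in and swells
#' it (alpha > 0).
#'
#' @param ion_params An [ion_params()] set carrying the beta sensitivities.
#' @param step Relative tension perturbation for the central difference.
#' @param check_tol Maximum allowed relative disagreement between the
#'   full-step and half-step derivative estimates.
#' @return alpha (dimensionless).
#' @export
mechanosensitivity_alpha <- function(ion_params, step = 1e-3,
                                     check_tol = 1e-3) {
  stopifnot(inherits(ion_params, "ion_params"))
  lnV_at <- function(eps) {
    ps <- ion_params
    ps$gNa <- ion_params$gNa * (1 + ion_params$betaNa * eps)
    ps$gK  <- ion_params$gK  * (1 + ion_params$betaK  * eps)
    ps$gCl <- ion_params$gCl * (1 + ion_params$betaCl * eps)
    log(solve_steady_state(ps)$V)
  }
  d_at <- function(hh) (lnV_at(hh) - lnV_at(-hh)) / (2 * hh)
  d1 <- d_at(step)
  d2 <- d_at(step / 2)
  # Richardson: central differences are O(h^2); extrapolate and check
  alpha <- (4 * d2 - d1) / 3
  if (abs(d1 - d2) > check_tol * max(1, abs(alpha))) {
    stop("mechanosensitivity_alpha: finite-difference estimates did not ",
         "converge (", signif(d1, 6), " vs ", signif(d2, 6),
         "); reduce `step`", call. = FALSE)
  }
  alpha
}

#' Maxwell tension response to a total-area history
#'
#' Integrates the Maxwell-fluid tension model
#' (1 + tau d/dt) dgamma/gamma_iso = (k tau / gamma_iso) dAtot/dt
#' driven by a log-total-area time series, with dgamma(0) = 0. A
#' trapezoidal (Crank-Nicolson) update gives O(dt^2) accuracy.
#'
#' @param times Uniformly spaced sample times (min).
#' @param lnAtot ln of total membrane area at `times`.
#' @param params A [mechano_params()] with `k` and `gamma_iso` set.
#' @return Numeric vector of relative tension dgamma/gamma_iso at `times`.
#' @export
tension_response <- function(times, lnAtot, params) {
  stopifnot(inherits(params, "mechano_params"))
  if (is.null(params$k) || is.null(params$gamma_iso)) {
    stop("tension_response: params must carry k and gamma_iso", call. = FALSE)
  }
  n <- length(times)
  if (length(lnAtot) != n || n < 2) {
    stop("tension_response: times and lnAtot must have equal length >= 2",
         call. = FALSE)
  }
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1]) {
    stop("tension_response: times must be uniformly sampled", call. = FALSE)
  }
  dt <- dt[1]
  tau <- params$tau
  kfac <- params$k * tau / params$gamma_iso
  Atot <- exp(lnAtot)
  # midpoint area rate; forcing F = kfac * dAtot/dt
  dA <- diff(Atot) / dt
  x <- numeric(n)
  # (x_{j+1} - x_j)/dt = ( -(x_j + x_{j+1})/2 + F_{j+1/2} ) / tau
  for (j in seq_len(n - 1)) {
    Fmid <- kfac * dA[j]
    x[j + 1] <- (x[j] * (1 - dt / (2 * tau)) + dt * Fmid / tau) /
      (1 + dt / (2 * tau))
  }
  x
}

#' Simulate volume and tension during cell spreading
#'
#' Integrates the mechanosensitive pump-and-leak volume dynamics during
#' spreading: the contact area follows the saturating ansatz, the total
#' membrane area and its partial derivatives come from the spherical-cap
#' geometry at each step, and the deviation u = dV/V_iso (relative to the
#' growing reference V_iso (1 + r t)) obeys
#'
#'   tau_eff du/dt = -u - xi tau (f1 V_iso r + f2 dAc/dt),
#'   tau_eff = tau (1 + xi V_iso f1),
#'
#' the reduction of the Maxwell tension model and the linear volume-tension
#' coupling onto the cap geometry. Growth enters as the constant source
#' V_iso * r_growth. Integration is a semi-implicit trapezoidal scheme
#' (implicit in u), O(dt^2), robust in the stiff fast-relaxation limit.
#'
#' @param params A [mechano_params()].
#' @param ansatz A [spreading_ansatz()].
#' @param duration Simulated time (min).
#' @param dt Step (min); default 0.1.
#' @param normalized If `TRUE` return V/V_iso instead of um^3.
#' @return A data.frame with `time_min`, `V` (or `V_norm`), `Ac`, `Atot`,
#'   `u` (relative volume deviation from the growth reference) and
#'   `tension` (dgamma/gamma_iso via the Maxwell model when `k` and
#'   `gamma_iso` are set, else via u/alpha when `alpha` is set, else NA).
#' @export
simulate_spreading_volume <- function(params, ansatz, duration = 60,
                                      dt = 0.1, normalized = FALSE) {
  stopifnot(inherits(params, "mechano_params"),
            inherits(ansatz, "spreading_ansatz"))
  if (duration <= 0 || dt <= 0) {
    stop("simulate_spreading_volume: duration and dt must be positive",
         call. = FALSE)
  }
  V_iso <- params$V_iso
  xi <- params$xi
  tau <- params$tau
  r <- params$r_growth / 60   # per minute
  times <- seq(0, duration, by = dt)
  n <- length(times)
  Ac <- pmax(ansatz_area(ansatz, times), 1e-6)
  dAc <- ansatz_area_rate(ansatz, times)

  u <- numeric(n)
  V <- numeric(n); V[1] <- V_iso
  Atot <- numeric(n)
  coefs <- function(V, Ac, dAc) {
    g <- cap_coefs_fast(V, Ac)
    tau_eff <- tau * (1 + xi * V_iso * g[["f1"]])
    if (tau_eff <= 0) {
      stop("simulate_spreading_volume: tau_eff <= 0 (unphysical xi/geometry ",
           "combination)", call. = FALSE)
    }
    list(Atot = g[["Atot"]],
         force = -xi * tau * (g[["f1"]] * V_iso * r + g[["f2"]] * dAc),
         tau_eff = tau_eff)
  }
  c0 <- coefs(V[1], Ac[1], dAc[1])
  Atot[1] <- c0$Atot
  for (j in seq_len(n - 1)) {
    # predictor (explicit) for the state at j+1, then trapezoidal corrector
    du_j <- (-u[j] + c0$force) / c0$tau_eff
    u_pred <- u[j] + dt * du_j
    V_pred <- V_iso * (1 + r * times[j + 1]) + V_iso * u_pred
    if (V_pred <= 0) {
      stop("simulate_spreading_volume: volume collapsed at t = ",
           signif(times[j + 1], 4), " min", call. = FALSE)
    }
    c1 <- coefs(V_pred, Ac[j + 1], dAc[j + 1])
    # u_{j+1} = u_j + dt/2 * (du_j + (-u_{j+1} + F_{j+1}) / tau_eff,j+1)
    u[j + 1] <- (u[j] + dt / 2 * (du_j + c1$force / c1$tau_eff)) /
      (1 + dt / (2 * c1$tau_eff))
    V[j + 1] <- V_iso * (1 + r * times[j + 1]) + V_iso * u[j + 1]
    if (V[j + 1] <= 0) {
      stop("simulate_spreading_volume: volume collapsed at t = ",
           signif(times[j + 1], 4), " min", call. = FALSE)
    }
    c1 <- coefs(V[j + 1], Ac[j + 1], dAc[j + 1])
    Atot[j + 1] <- c1$Atot
    c0 <- c1
  }

  tension <- rep(NA_real_, n)
  if (!is.null(params$k) && !is.null(params$gamma_iso)) {
    tension <- tension_response(times, log(Atot), params)
  } else if (!is.null(params$alpha) && params$alpha != 0) {
    tension <- u / params$alpha
  }
  out <- data.frame(time_min = times,
                    Ac = Ac, Atot = Atot, u = u, tension = tension)
  if (normalized) out$V_norm <- V / V_iso else out$V <- V
  out
}

#' Predicted tension excess when mechano-osmotic coupling is absent
#'
#' Runs the spreading simulation twice — once with the given coupling and
#' once with alpha = 0 (xi = 0, volume follows growth only) — and returns
#' the difference tension(alpha = 0) - tension(coupled) at each time. With
#' coupling, volume loss moderates the total-area increase, so the
#' uncoupled cell transiently carries the higher tension; the difference
#' peaks during the spreading phase and relaxes to zero.
#'
#' @inheritParams simulate_spreading_volume
#' @return A data.frame with `time_min`, `tension_uncoupled`,
#'   `tension_coupled` and `diff`.
#' @export
tension_difference_without_coupling <- function(params, ansatz,
                                                duration = 60, dt = 0.1) {
  stopifnot(inherits(params, "mechano_params"))
  if (is.null(params$k) || is.null(params$gamma_iso)) {
    stop("tension_difference_without_coupling: params must carry k and ",
         "gamma_iso for the Maxwell tension output", call. = FALSE)
  }
  p0 <- params
  p0$xi <- 0
  p0$alpha <- if (!is.null(params$alpha)) 0 else NULL
  sim_c <- simulate_spreading_volume(params, ansatz, duration, dt)
  sim_0 <- simulate_spreading_volume(p0, ansatz, duration, dt)
  data.frame(time_min = sim_c$time_min,
             tension_uncoupled = sim_0$tension,
             tension_coupled = sim_c$tension,
             diff = sim_0$tension - sim_c$tension)
}

#' Volume coefficient of variation of a migrating cell
#'
#' A cell migrating at `speed` through a matrix with characteristic
#' constriction spacing experiences area-strain forcing at angular
#' frequency omega = 2 pi speed / mesh_spacing. Filtering a sinusoidal
#' forcing of amplitude epsilon through the viscoelastic volume model gives
#' the root-mean-square relative volume fluctuation
#'
#'   CV(v) = xi * omega * tau * epsilon / (sqrt(2) sqrt(1 + (omega tau_eff)^2)),
#'
#' zero at rest, increasing with speed, saturating at
#' xi epsilon tau / (sqrt(2) tau_eff).
#'
#' @param speed Migration speed(s), um/min, >= 0. Vectorised.
#' @param params A [migration_params()].
#' @return CV (dimensionless).
#' @export
migration_cv_model <- function(speed, params) {
  stopifnot(inherits(params, "migration_params"))
  if (any(speed < 0)) {
    stop("migration_cv_model: speed must be >= 0", call. = FALSE)
  }
  omega <- 2 * pi * speed / params$mesh_spacing
  params$xi * omega * params$tau * params$forcing_amplitude /
    (sqrt(2) * sqrt(1 + (omega * params$tau_eff)^2))
}

#' Fit the migration CV model to (speed, CV) points
#'
#' Only two lumped parameters are identifiable from CV-versus-speed data:
#' the amplitude xi * epsilon * tau and the effective relaxation time
#' tau_eff. They are fitted by nonlinear least squares
#' ([minpack.lm::nlsLM()]); the individual factors of the amplitude are
#' degenerate and are not resolved.
#'
#' @param speeds,cvs Numeric vectors (>= 4 points, non-negative speeds with
#'   spread).
#' @param mesh_spacing Constriction spacing (um), fixed during the fit.
#' @param start Optional named list with `amp` and `tau_eff` starting
#'   values.
#' @return A list of class `migration_cv_fit` with `amp` (= xi epsilon tau,
#'   min), `tau_eff` (min), `residual_norm`, `converged`, `n` and the
#'   underlying `fit` object.
#' @export
fit_migration_cv <- function(speeds, cvs, mesh_spacing = 50, start = NULL) {
  if (length(speeds) != length(cvs) || length(speeds) < 4) {
    stop("fit_migration_cv: need >= 4 (speed, CV) points", call. = FALSE)
  }
  if (any(speeds < 0)) {
    stop("fit_migration_cv: speeds must be >= 0", call. = FALSE)
  }
  if (stats::sd(speeds) == 0) {
    stop("fit_migration_cv: degenerate data (all speeds equal)",
         call. = FALSE)
  }
  if (all(cvs == 0)) {
    return(structure(list(amp = 0, tau_eff = NA_real_, residual_norm = 0,
                          converged = TRUE, n = length(speeds), fit = NULL),
                     class = "migration_cv_fit"))
  }
  omega <- 2 * pi * speeds / mesh_spacing
  df <- data.frame(omega = omega, cv = cvs)
  if (is.null(start)) {
    start <- list(amp = max(cvs) * sqrt(2) / max(omega[omega > 0]),
                  tau_eff = 1 / stats::median(omega[omega > 0]))
  }
  fit <- minpack.lm::nlsLM(
    cv ~ amp * omega / (sqrt(2) * sqrt(1 + (omega * tau_eff)^2)),
    data = df, start = start,
    lower = c(amp = 0, tau_eff = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  structure(list(amp = unname(est["amp"]), tau_eff = unname(est["tau_eff"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv, n = length(speeds),
                 fit = fit),
            class = "migration_cv_fit")
}
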