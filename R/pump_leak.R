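#' Steady state of the pump-and-leak model
#'
#' Solves for the cell state at which (i) each ion species carries zero net
#' flux (Ohmic passive flux g_i (Vm - E_i) with Nernst potential E_i, plus
#' the electrogenic 3Na:2K pump on sodium and potassium), (ii) the interior
#' is electroneutral including the charged impermeant osmolytes, and
#' (iii) the interior is in osmotic balance with the medium.
#'
#' The zero-flux conditions give each internal concentration in closed form
#' as a function of the membrane potential; the difference of the
#' electroneutrality and osmotic-balance conditions then gives the water
#' volume as a function of Vm, leaving a single scalar root problem in Vm.
#'
#' @param params An [ion_params()] set.
#' @param V_init_guess Initial volume guess (um^3); used only to scale the
#'   bracket search, the reduced problem does not need a good guess.
#' @return An object of class `osmotic_state`: a list with total volume `V`,
#'   water volume `Vw`, excluded volume `b`, internal concentrations
#'   `cNa`, `cK`, `cCl` (mM), membrane potential `Vm` (mV), membrane area
#'   `A` (um^2, spherical), and the residuals of the three balance
#'   conditions.
#' @export
solve_steady_state <- function(params, V_init_guess = params$V_iso) {
  stopifnot(inherits(params, "ion_params"))
  if (V_init_guess <= 0) {
    stop("solve_steady_state: V_init_guess must be positive", call. = FALSE)
  }
  p <- params
  vt <- THERMAL_VOLTAGE_MV
  if (p$gNa <= 0 || p$gK <= 0 || p$gCl <= 0) {
    stop("solve_steady_state: all conductances must be positive for a ",
         "determinate steady state", call. = FALSE)
  }
  n_imp <- (1 - p$zX) * p$nX + p$nY
  if (n_imp <= 0) {
    stop("solve_steady_state: no impermeant osmolytes (nX = nY = 0): cell ",
         "volume is undetermined in the pump-and-leak model", call. = FALSE)
  }
  Pi_ext <- p$cNa_ext + p$cK_ext + p$cCl_ext

  cNa_of <- function(Vm) p$cNa_ext * exp(-(Vm + 3 * p$pump_rate / p$gNa) / vt)
  cK_of  <- function(Vm) p$cK_ext  * exp(-(Vm - 2 * p$pump_rate / p$gK) / vt)
  cCl_of <- function(Vm) p$cCl_ext * exp(Vm / vt)
  Vw_of  <- function(Vm) n_imp / (Pi_ext - 2 * cCl_of(Vm))

  # Electroneutrality residual after eliminating Vw via osmotic balance
  F_of <- function(Vm) {
    cNa_of(Vm) + cK_of(Vm) - cCl_of(Vm) + p$zX * p$nX / Vw_of(Vm)
  }

  Vm_max <- vt * log(Pi_ext / (2 * p$cCl_ext))  # Vw > 0 requires Vm < Vm_max
  grid <- seq(Vm_max - 1e-6, Vm_max - 300, length.out = 600)
  fv <- vapply(grid, F_of, numeric(1))
  sign_change <- which(diff(sign(fv)) != 0)
  if (length(sign_change) == 0) {
    stop("solve_steady_state: no positive-volume steady state found ",
         "(classical pump-off divergence or unphysical parameters); ",
         "min |residual| on scan = ", signif(min(abs(fv)), 4), " mM",
         call. = FALSE)
  }
  i <- sign_change[1]
  root <- stats::uniroot(F_of, lower = grid[i + 1], upper = grid[i],
                         tol = 1e-13)
  Vm <- root$root
  cNa <- cNa_of(Vm); cK <- cK_of(Vm); cCl <- cCl_of(Vm)
  Vw <- Vw_of(Vm)
  b <- p$excluded_fraction * p$V_iso
  V <- Vw + b

  res_en <- cNa + cK - cCl + p$zX * p$nX / Vw
  res_os <- cNa + cK + cCl + (p$nX + p$nY) / Vw - Pi_ext
  res_flux <- c(
    Na = p$gNa * (Vm - vt * log(p$cNa_ext / cNa)) + 3 * p$pump_rate,
    K  = p$gK  * (Vm - vt * log(p$cK_ext / cK)) - 2 * p$pump_rate,
    Cl = p$gCl * (Vm + vt * log(p$cCl_ext / cCl)))
  rel <- max(abs(c(res_en, res_os)) / Pi_ext, abs(res_flux) / max(1, p$pump_rate))
  if (rel > 1e-8) {
    stop("solve_steady_state: converged root fails residual check ",
         "(relative residual ", signif(rel, 3), ")", call. = FALSE)
  }
  structure(list(V = V, Vw = Vw, b = b,
                 cNa = cNa, cK = cK, cCl = cCl, Vm = Vm,
                 A = sphere_area_from_volume(V),
                 residuals = c(electroneutrality = res_en,
                               osmotic = res_os, res_flux)),
            class = "osmotic_state")
}

#' Passive (Ponder) post-shock volume
#'
#' Immediately after an osmotic shock, water equilibrates in seconds at
#' fixed solute content, so the normalised volume is affine in the inverse
#' relative osmolarity: V/V_iso = R * (Piso/P) + (1 - R), where R is the
#' osmotically active volume fraction and 1 - R the osmotically inactive
#' (excluded) fraction.
#'
#' @param ratio Piso/P, the isosmotic-to-imposed external osmolarity ratio
#'   (> 1 for hypo-osmotic shocks).
#' @param active_fraction R, in (0, 1].
#' @return Normalised volume V/V_iso.
#' @export
ponder_passive_volume <- function(ratio, active_fraction) {
  if (any(ratio <= 0)) {
    stop("ponder_passive_volume: ratio must be positive", call. = FALSE)
  }
  if (active_fraction <= 0 || active_fraction > 1) {
    stop("ponder_passive_volume: active_fraction must be in (0, 1]",
         call. = FALSE)
  }
  active_fraction * ratio + (1 - active_fraction)
}

#' Shock protocol
#'
#' An ordered sequence of medium exchanges. Each event sets the external
#' osmolarity to Pi_iso / ratio (so ratio Piso/P = 2 is a two-fold dilution,
#' a hypo-osmotic shock).
#'
#' @param times_s Event times in seconds, strictly increasing, first >= 0.
#' @param ratios Piso/P per event, all positive.
#' @param duration Total simulated time (s).
#' @param dt Output sampling interval (s).
#' @return An object of class `shock_protocol`.
#' @export
shock_protocol <- function(times_s, ratios, duration, dt = 1) {
  if (length(times_s) != length(ratios) || length(times_s) == 0) {
    stop("shock_protocol: times_s and ratios must have equal positive length",
         call. = FALSE)
  }
  if (any(diff(times_s) <= 0)) {
    stop("shock_protocol: event times must be strictly increasing",
         call. = FALSE)
  }
  if (any(ratios <= 0)) {
    stop("shock_protocol: osmolarity ratios must be positive", call. = FALSE)
  }
  if (duration <= max(times_s)) {
    stop("shock_protocol: duration must exceed the last event time",
         call. = FALSE)
  }
  if (dt <= 0) stop("shock_protocol: dt must be positive", call. = FALSE)
  structure(list(times_s = times_s, ratios = ratios,
                 duration = duration, dt = dt),
            class = "shock_protocol")
}

#' Simulate the dynamic response to osmotic shocks
#'
#' Integrates the two-timescale shock response: water flux
#' dV/dt = Lp A (Pi_int - Pi_ext) equilibrates the osmotic imbalance within
#' seconds (with `Lp_in` during swelling and `Lp_out` during shrinking),
#' while over minutes the regulatory machinery moves ions as electroneutral
#' KCl pairs at rate `k_reg` towards the total ion content that restores
#' the isosmotic cell volume under the current medium — the classical
#' regulatory volume decrease/increase (KCl efflux after swelling, influx
#' after shrinking), implemented as first-order relaxation with an optional
#' saturating cap `max_reg_flux` that reproduces the partial recovery seen
#' after large shocks. The impermeant osmolyte amounts nX and nY are
#' conserved exactly: fast volume changes carry water and ions, never dry
#' mass.
#'
#' @param params An [ion_params()] set.
#' @param state0 Initial state from [solve_steady_state()] (must be the
#'   steady state of `params` within 0.1 % on volume-relevant residuals).
#' @param protocol A [shock_protocol()].
#' @param times_s Optional explicit output times (s), overriding the
#'   protocol's uniform `dt` grid (useful for fast/slow two-phase sampling).
#' @return An object of class `osmotic_trajectory`: a data.frame with
#'   columns `time_s`, `V` (um^3), `nNa`, `nK`, `nCl` (mM um^3) and
#'   `osm_ext` (mM), with the parameter set attached as an attribute.
#' @export
simulate_osmotic_shock <- function(params, state0, protocol, times_s = NULL) {
  stopifnot(inherits(params, "ion_params"),
            inherits(state0, "osmotic_state"),
            inherits(protocol, "shock_protocol"))
  p <- params
  b <- state0$b
  Pi_iso <- p$cNa_ext + p$cK_ext + p$cCl_ext
  A <- state0$A

  # steady-state consistency of state0 with params
  chk <- solve_steady_state(p)
  if (abs(chk$V - state0$V) > 1e-3 * state0$V) {
    stop("simulate_osmotic_shock: state0 is not the steady state of params ",
         "(volume differs by ", signif(abs(chk$V - state0$V) / state0$V, 3),
         " relative)", call. = FALSE)
  }

  # water-flux timescale; refuse output sampling far too coarse to resolve it
  tau_w_min <- state0$Vw / (max(p$Lp_in, p$Lp_out) * A * p$RT * Pi_iso)
  if (is.null(times_s) && protocol$dt > 10 * tau_w_min * 60) {
    stop("simulate_osmotic_shock: output dt = ", protocol$dt, " s is too ",
         "coarse for the passive water-flux timescale (",
         signif(tau_w_min * 60, 3), " s); refine protocol dt", call. = FALSE)
  }

  if (is.null(times_s)) {
    times_s <- seq(0, protocol$duration, by = protocol$dt)
  }
  times_s <- sort(unique(c(times_s, protocol$times_s, protocol$duration)))
  times_s <- times_s[times_s >= 0 & times_s <= protocol$duration]

  # per-segment external medium and regulatory target content
  seg_start <- c(0, protocol$times_s)
  seg_ratio <- c(1, protocol$ratios)
  keep <- !duplicated(seg_start, fromLast = TRUE)
  seg_start <- seg_start[keep]; seg_ratio <- seg_ratio[keep]
  seg_end <- c(seg_start[-1], protocol$duration)

  Vw_iso <- state0$Vw

  y <- c(V = state0$V,
         nNa = state0$cNa * state0$Vw,
         nK = state0$cK * state0$Vw,
         nCl = state0$cCl * state0$Vw)
  out <- NULL
  for (s in seq_along(seg_start)) {
    t0 <- seg_start[s]; t1 <- seg_end[s]
    if (t1 <= t0) next
    ratio <- seg_ratio[s]
    osm_ext <- Pi_iso / ratio
    # ion content restoring the isosmotic water volume under this medium
    n_target <- osm_ext * Vw_iso - p$nX - p$nY
    deriv <- function(t, y, parms) {
      Vw <- y[1] - b
      if (Vw <= 0) return(list(rep(0, 4)))
      osm_int <- (y[2] + y[3] + y[4] + p$nX + p$nY) / Vw
      dPi <- p$RT * (osm_int - osm_ext)          # Pa; > 0 -> water enters
      Lp <- if (dPi > 0) p$Lp_in else p$Lp_out
      dV <- Lp * A * dPi / 60                    # per-second rates
      dn <- c(0, 0, 0)
      if (p$k_reg > 0) {
        # electroneutral KCl flux towards the target total content
        fx <- p$k_reg * (y[2] + y[3] + y[4] - n_target) / 60
        fx <- min(max(fx, -p$max_reg_flux / 60), p$max_reg_flux / 60)
        if (fx > 0 && (y[3] <= 0 || y[4] <= 0)) fx <- 0
        dn <- c(0, -fx / 2, -fx / 2)
      }
      list(c(dV, dn))
    }
    tt <- times_s[times_s >= t0 & times_s <= t1]
    tt <- sort(unique(c(t0, tt, t1)))
    sol <- deSolve::ode(y = y, times = tt, func = deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-9, atol = 1e-9)
    if (any(sol[, "V"] <= b)) {
      t_fail <- sol[which(sol[, "V"] <= b)[1], "time"]
      stop("simulate_osmotic_shock: volume collapsed to the excluded volume ",
           "at t = ", signif(t_fail, 4), " s", call. = FALSE)
    }
    seg_df <- as.data.frame(sol)
    seg_df$osm_ext <- osm_ext
    out <- if (is.null(out)) seg_df else rbind(out[out$time < t0, ], seg_df)
    y <- unlist(seg_df[nrow(seg_df), c("V", "nNa", "nK", "nCl")])
    names(y) <- c("V", "nNa", "nK", "nCl")
  }
  out <- out[out$time %in% times_s, ]
  names(out)[names(out) == "time"] <- "time_s"
  rownames(out) <- NULL
  structure(out, class = c("osmotic_trajectory", "data.frame"),
            params = p, b = b, V_iso = state0$V)
}

#' Estimate hydraulic permeability from the passive shock response
#'
#' During the first seconds after a shock the volume changes linearly at
#' rate Lp * A * dPi; the permeability is recovered as the absolute initial
#' slope of V(t) over a user-designated linear region, divided by membrane
#' area and osmotic pressure step.
#'
#' @param trace An `osmotic_trajectory` (or data.frame with `time_s`, `V`).
#' @param area Membrane area used for flux scaling (um^2).
#' @param delta_Pi Imposed osmotic pressure step (Pa), non-zero.
#' @param region_s Length-2 numeric: time window (s) of the linear region.
#'   Defaults to the first three samples after the shock at t = 0.
#' @return Lp in um min^-1 Pa^-1.
#' @export
estimate_permeability <- function(trace, area, delta_Pi, region_s = NULL) {
  if (area <= 0) stop("estimate_permeability: area must be positive",
                      call. = FALSE)
  if (abs(delta_Pi) == 0) {
    stop("estimate_permeability: delta_Pi must be non-zero", call. = FALSE)
  }
  tt <- trace$time_s; V <- trace$V
  if (is.null(region_s)) {
    idx <- which(tt >= 0)[seq_len(min(3, sum(tt >= 0)))]
  } else {
    idx <- which(tt >= region_s[1] & tt <= region_s[2])
  }
  if (length(idx) < 3) {
    stop("estimate_permeability: fewer than 3 samples in the linear region",
         call. = FALSE)
  }
  slope_s <- unname(stats::coef(stats::lm(V[idx] ~ tt[idx]))[2])  # um^3/s
  abs(slope_s) * 60 / (area * abs(delta_Pi))
}

#' Regulatory adaptation rate after an osmotic shock
#'
#' Locates the volume extremum of the passive response (discrete
#' argmin/argmax over the first 3 min after the shock, earliest sample on
#' ties) and returns the ordinary least-squares slope of V(t) over the
#' 5-minute window starting at that extremum.
#'
#' @param trace An `osmotic_trajectory` with the shock at t = 0.
#' @param search_min Extremum search horizon after the shock (min).
#' @param window_min Slope window length (min).
#' @return Adaptation flux in um^3/min (negative for recovery from swelling).
#' @export
adaptation_rate <- function(trace, search_min = 3, window_min = 5) {
  tt <- trace$time_s; V <- trace$V
  post <- which(tt >= 0 & tt <= search_min * 60)
  if (length(post) < 3) {
    stop("adaptation_rate: too few samples in the extremum search window",
         call. = FALSE)
  }
  V0 <- V[post[1]]
  dev <- abs(V[post] - V0)
  i_ext <- post[which.max(dev)]
  if (max(dev) <= .Machine$double.eps^0.5 * max(1, V0)) {
    stop("adaptation_rate: no extremum detectable (flat or monotone trace)",
         call. = FALSE)
  }
  t_ext <- tt[i_ext]
  if (max(tt) < t_ext + window_min * 60) {
    stop("adaptation_rate: trace does not span ", window_min,
         " min after the extremum", call. = FALSE)
  }
  win <- which(tt >= t_ext & tt <= t_ext + window_min * 60)
  if (length(win) < 3) {
    stop("adaptation_rate: fewer than 3 samples in the slope window",
         call. = FALSE)
  }
  t_min <- tt[win] / 60
  unname(stats::coef(stats::lm(V[win] ~ t_min))[2])
}

#' Osmotic bulk modulus
#'
#' B = V_iso * dP / dV: the apparent volumetric stiffness of the cell under
#' an osmotic pressure step.
#'
#' @param V_iso Isosmotic volume (um^3).
#' @param delta_P Osmotic pressure change (Pa).
#' @param delta_V Resulting volume change (um^3), non-zero, same sign
#'   convention as `delta_P`.
#' @return B in Pa.
#' @export
bulk_modulus <- function(V_iso, delta_P, delta_V) {
  if (delta_V == 0) stop("bulk_modulus: delta_V must be non-zero",
                         call. = FALSE)
  V_iso * delta_P / delta_V
}

#' Laplace pressure across a curved cortex
#'
#' @param gamma Surface tension (mN/m).
#' @param radius Radius of curvature (um); positive.
#' @return 2 * gamma / radius in Pa (1 mN/m over 10 um is 100 Pa per factor
#'   of 2, i.e. 200 Pa here).
#' @export
laplace_pressure <- function(gamma, radius) {
  if (radius <= 0) stop("laplace_pressure: radius must be positive",
                        call. = FALSE)
  2 * gamma * 1e-3 / (radius * 1e-6)  # SI: N/m over m -> Pa
}

#' Osmotic pressure change of trapped osmolytes under volume loss
#'
#' A relative volume decrease `f` concentrates the impermeant osmolytes,
#' raising their osmotic pressure by Pi * f to linear order (the exact
#' concentration-ratio form Pi * f / (1 - f) is also returned).
#'
#' @param Pi_trapped Osmotic pressure of the trapped osmolytes (Pa).
#' @param volume_decrease_fraction Relative volume decrease, in [0, 1).
#' @return List with `linearized` and `exact` pressure changes (Pa).
#' @export
trapped_pressure_change <- function(Pi_trapped, volume_decrease_fraction) {
  f <- volume_decrease_fraction
  if (f < 0 || f >= 1) {
    stop("trapped_pressure_change: fraction must be in [0, 1)", call. = FALSE)
  }
  list(linearized = Pi_trapped * f,
       exact = Pi_trapped * f / (1 - f))
}

#' Upper bound on the volume change achievable by cortical contractility
#'
#' Balancing an increased cortical Laplace pressure against the osmotic
#' pressure scale of the impermeant osmolytes bounds the relative volume
#' change contractility can impose: even a ten-fold tension increase over a
#' ~100 Pa baseline only re-concentrates a ~1e5 Pa osmolyte reservoir by
#' about one percent.
#'
#' @param tension_factor Fold increase in cortical tension (>= 0).
#' @param P_laplace_base Baseline cortical Laplace pressure (Pa).
#' @param Pi_total Osmotic pressure scale it must work against (Pa), > 0.
#' @return Relative volume change (dimensionless).
#' @export
contractility_volume_bound <- function(tension_factor, P_laplace_base,
                                       Pi_total) {
  if (Pi_total <= 0) {
    stop("contractility_volume_bound: Pi_total must be positive",
         call. = FALSE)
  }
  if (tension_factor < 0) {
    stop("contractility_volume_bound: tension_factor must be >= 0",
         call. = FALSE)
  }
  tension_factor * P_laplace_base / Pi_total
}
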