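#' Ion-transport parameter set for the pump-and-leak model
#'
#' Bundles the external medium composition, the passive membrane conductance
#' of each monovalent ion with its tension sensitivity, the active sodium
#' pump rate (fixed 3Na-out : 2K-in stoichiometry), the impermeant osmolyte
#' content of the cell, the hydraulic water permeability (asymmetric between
#' swelling and shrinking), and the regulatory ion-content relaxation rate.
#'
#' Units follow a consistent micrometre/minute/millimolar/Pascal/millivolt
#' system: concentrations in mM, conductances in amount min^-1 um^-2 mV^-1,
#' pump rate in amount min^-1 um^-2, osmolyte amounts in mM um^3, hydraulic
#' permeabilities in um min^-1 Pa^-1, rates in min^-1. `RT` converts an
#' osmolarity in mM to an osmotic pressure in Pa (van 't Hoff; 2577 Pa/mM at
#' 310 K) and the thermal voltage RT/F is fixed internally at 26.71 mV.
#'
#' @param cNa_ext,cK_ext,cCl_ext External ion concentrations (mM). The
#'   external medium must be electroneutral: cNa_ext + cK_ext = cCl_ext.
#' @param gNa,gK,gCl Passive conductances per unit membrane area.
#' @param betaNa,betaK,betaCl Dimensionless tension sensitivities of the
#'   conductances: g_i(gamma) = g_i * (1 + beta_i * dgamma/gamma_iso).
#' @param pump_rate Active Na extrusion rate per unit area (3Na:2K).
#' @param nX Amount of charged impermeant osmolyte (mM um^3).
#' @param zX Mean valence of X; negative (cytoplasmic macromolecules carry a
#'   net negative charge).
#' @param nY Amount of neutral impermeant osmolyte (mM um^3).
#' @param Lp_in,Lp_out Hydraulic permeability for water entry (swelling) and
#'   exit (shrinking), um min^-1 Pa^-1.
#' @param k_reg Regulatory ion-content relaxation rate (min^-1).
#' @param max_reg_flux Optional cap on the absolute regulatory ion flux
#'   (mM um^3 min^-1 per species); `Inf` disables the cap. A finite cap
#'   reproduces the partial recovery seen after large hypo-osmotic shocks.
#' @param excluded_fraction Osmotically inactive volume fraction b/V_iso.
#' @param V_iso Reference isosmotic volume (um^3) used to convert
#'   `excluded_fraction` into the absolute excluded volume b.
#' @param RT van 't Hoff conversion factor (Pa per mM).
#'
#' @return An object of class `ion_params` (a validated list).
#' @seealso [default_ion_params()] for the calibrated default set,
#'   [solve_steady_state()], [simulate_osmotic_shock()].
#' @export
ion_params <- function(cNa_ext = 145, cK_ext = 5, cCl_ext = 150,
                       gNa = 1, gK = 1, gCl = 1,
                       betaNa = 0, betaK = 0, betaCl = 0,
                       pump_rate = 30,
                       nX = 134000, zX = -0.7, nY = 0,
                       Lp_in = 2e-5, Lp_out = 1e-5,
                       k_reg = 0.1, max_reg_flux = Inf,
                       excluded_fraction = 0.33,
                       V_iso = 2000,
                       RT = 2577) {
  p <- list(cNa_ext = cNa_ext, cK_ext = cK_ext, cCl_ext = cCl_ext,
            gNa = gNa, gK = gK, gCl = gCl,
            betaNa = betaNa, betaK = betaK, betaCl = betaCl,
            pump_rate = pump_rate,
            nX = nX, zX = zX, nY = nY,
            Lp_in = Lp_in, Lp_out = Lp_out,
            k_reg = k_reg, max_reg_flux = max_reg_flux,
            excluded_fraction = excluded_fraction,
            V_iso = V_iso, RT = RT)
  class(p) <- "ion_params"
  validate_ion_params(p)
  p
}

validate_ion_params <- function(p, tol = 1e-6) {
  nonneg <- c("cNa_ext", "cK_ext", "cCl_ext", "gNa", "gK", "gCl",
              "pump_rate", "nX", "nY", "Lp_in", "Lp_out", "k_reg",
              "V_iso", "RT")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) ||
        p[[f]] < 0) {
      stop("ion_params: '", f, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (p$zX >= 0) {
    stop("ion_params: zX must be negative (impermeant macromolecules carry ",
         "net negative charge)", call. = FALSE)
  }
  if (p$excluded_fraction < 0 || p$excluded_fraction >= 1) {
    stop("ion_params: excluded_fraction must lie in [0, 1)", call. = FALSE)
  }
  imbalance <- p$cNa_ext + p$cK_ext - p$cCl_ext
  if (abs(imbalance) > tol * max(1, p$cCl_ext)) {
    stop("ion_params: external medium not electroneutral ",
         "(cNa_ext + cK_ext - cCl_ext = ", signif(imbalance, 4), " mM)",
         call. = FALSE)
  }
  invisible(p)
}

# Thermal voltage RT/F in mV at 310 K (8.314*310/96485 volts).
THERMAL_VOLTAGE_MV <- 1000 * 8.314 * 310 / 96485

#' Default calibrated ion-transport parameters
#'
#' Returns an [ion_params()] set whose steady state reproduces the textbook
#' mammalian-cell interior used throughout: external Na/K/Cl of 145/5/150 mM
#' (300 mM total), internal targets cNa = 15, cK = 120, cCl = 65 mM
#' (200 mM of ions) plus 100 mM of impermeant osmolytes with mean valence
#' -0.7, at a reference volume of 2000 um^3 with a 0.33 osmotically inactive
#' fraction. The sodium and potassium conductances are derived from those
#' targets via the zero-flux conditions, so [solve_steady_state()] on this
#' set recovers the target composition to solver precision.
#'
#' @param ... Overrides forwarded to [ion_params()] after the calibrated
#'   conductances are computed (overriding `gNa`/`gK`/`pump_rate` breaks the
#'   calibration, intentionally so for perturbation studies).
#' @return An `ion_params` object.
#' @export
default_ion_params <- function(...) {
  # Target steady interior
  cNa <- 15; cK <- 120; cCl <- 65
  cNa_ext <- 145; cK_ext <- 5; cCl_ext <- 150
  vt <- THERMAL_VOLTAGE_MV
  Vm <- vt * log(cCl / cCl_ext)            # Cl passively equilibrated
  pump <- 30
  # zero net Na flux: gNa*(Vm - E_Na) + 3*pump = 0
  gNa <- 3 * pump / (vt * log(cNa_ext / cNa) - Vm)
  # zero net K flux: gK*(Vm - E_K) - 2*pump = 0
  gK <- 2 * pump / (Vm - vt * log(cK_ext / cK))
  V_iso <- 2000; excluded_fraction <- 0.33
  Vw <- V_iso * (1 - excluded_fraction)
  zX <- -0.7
  nX <- -(cNa + cK - cCl) * Vw / zX        # internal electroneutrality
  nY <- max(0, (cNa_ext + cK_ext + cCl_ext - cNa - cK - cCl) * Vw - nX)
  args <- list(cNa_ext = cNa_ext, cK_ext = cK_ext, cCl_ext = cCl_ext,
               gNa = gNa, gK = gK, gCl = 1, pump_rate = pump,
               nX = nX, zX = zX, nY = nY,
               excluded_fraction = excluded_fraction, V_iso = V_iso)
  override <- list(...)
  args[names(override)] <- override
  do.call(ion_params, args)
}

#' Mechanosensitive-coupling parameter set
#'
#' Parameters of the viscoelastic volume-tension model: the tension dynamics
#' are Maxwell-like, (1 + tau d/dt) dgamma/gamma_iso = (k tau/gamma_iso)
#' dAtot/dt, and relative volume tracks relative tension with logarithmic
#' sensitivity `alpha`, giving the effective stiffness
#' xi = -Atot k alpha / gamma_iso that converts the relative rate of total
#' membrane-area change into volume loss.
#'
#' Either supply `xi` directly (as the trajectory fits do), or supply
#' (`alpha`, `k`, `gamma_iso`, `Atot_iso`) and `xi` is derived; supplying
#' both triggers a consistency check.
#'
#' @param xi Dimensionless effective stiffness (>= 0 for volume loss).
#' @param tau Bare tension relaxation time (min).
#' @param alpha Dimensionless mechanosensitivity d ln V / d(dgamma/gamma_iso);
#'   negative for volume loss under tension.
#' @param k Tension elastic modulus per unit area change (mN m^-1 um^-2).
#' @param gamma_iso Resting membrane tension (mN/m).
#' @param Atot_iso Resting total membrane area (um^2), used only to tie
#'   `xi` to (`alpha`, `k`, `gamma_iso`).
#' @param r_growth Volume growth rate as a fraction per hour (0.05 = 5 %/hr).
#' @param V_iso Reference volume (um^3).
#' @return An object of class `mechano_params`.
#' @export
mechano_params <- function(xi = NULL, tau = 15,
                           alpha = NULL, k = NULL, gamma_iso = NULL,
                           Atot_iso = NULL,
                           r_growth = 0.05, V_iso = 2000) {
  if (tau <= 0) stop("mechano_params: tau must be positive", call. = FALSE)
  if (V_iso <= 0) stop("mechano_params: V_iso must be positive", call. = FALSE)
  derived <- NULL
  if (!is.null(alpha) && !is.null(k) && !is.null(gamma_iso) &&
      !is.null(Atot_iso)) {
    if (gamma_iso <= 0) {
      stop("mechano_params: gamma_iso must be positive", call. = FALSE)
    }
    if (k < 0) stop("mechano_params: k must be non-negative", call. = FALSE)
    derived <- -Atot_iso * k * alpha / gamma_iso
  }
  if (is.null(xi)) {
    if (is.null(derived)) {
      stop("mechano_params: supply xi, or all of alpha, k, gamma_iso, ",
           "Atot_iso", call. = FALSE)
    }
    xi <- derived
  } else if (!is.null(derived) &&
             abs(xi - derived) > 1e-8 * max(1, abs(xi))) {
    stop("mechano_params: xi inconsistent with -Atot_iso*k*alpha/gamma_iso ",
         "(", signif(xi, 6), " vs ", signif(derived, 6), ")", call. = FALSE)
  }
  p <- list(xi = xi, tau = tau, alpha = alpha, k = k,
            gamma_iso = gamma_iso, Atot_iso = Atot_iso,
            r_growth = r_growth, V_iso = V_iso)
  class(p) <- "mechano_params"
  p
}

#' Exponential-saturation contact-area model
#'
#' The cell-substrate contact area during spreading is described by
#' Ac(t) = A_init + (A0 - A_init) * (1 - exp(-t / tau_a)): an exponentially
#' saturating rise from the area at spreading onset to a plateau, with a
#' single spreading timescale.
#'
#' @param A_init Contact area at spreading onset (um^2).
#' @param A0 Saturating contact area (um^2); must exceed `A_init`.
#' @param tau_a Spreading timescale (min).
#' @return An object of class `spreading_ansatz`; call it indirectly via
#'   [ansatz_area()] / [ansatz_area_rate()].
#' @export
spreading_ansatz <- function(A_init, A0, tau_a) {
  if (A_init < 0) stop("spreading_ansatz: A_init must be >= 0", call. = FALSE)
  if (A0 <= A_init) stop("spreading_ansatz: A0 must exceed A_init",
                         call. = FALSE)
  if (tau_a <= 0) stop("spreading_ansatz: tau_a must be positive",
                       call. = FALSE)
  structure(list(A_init = A_init, A0 = A0, tau_a = tau_a),
            class = "spreading_ansatz")
}

#' Contact area and its rate under the saturating-spreading model
#'
#' @param ansatz A [spreading_ansatz()].
#' @param t Time(s) in minutes from spreading onset.
#' @return `ansatz_area`: contact area (um^2); `ansatz_area_rate`: its time
#'   derivative (um^2/min).
#' @export
ansatz_area <- function(ansatz, t) {
  ansatz$A_init + (ansatz$A0 - ansatz$A_init) * (1 - exp(-t / ansatz$tau_a))
}

#' @rdname ansatz_area
#' @export
ansatz_area_rate <- function(ansatz, t) {
  (ansatz$A0 - ansatz$A_init) / ansatz$tau_a * exp(-t / ansatz$tau_a)
}

#' Migration volume-fluctuation model parameters
#'
#' A cell migrating through a fibrous matrix is deformed each time it
#' squeezes past a constriction; this is idealised as a sinusoidal relative
#' total-area forcing of amplitude `forcing_amplitude` at angular frequency
#' omega = 2*pi*speed/mesh_spacing, filtered through the viscoelastic
#' volume-tension model (xi, tau, tau_eff).
#'
#' @param forcing_amplitude Dimensionless area-strain amplitude per
#'   constriction encounter.
#' @param mesh_spacing Characteristic distance between successive
#'   deformation events along the track (um).
#' @param xi,tau,tau_eff As in [mechano_params()]; `tau_eff` is the
#'   effective volume relaxation time (min).
#' @return An object of class `migration_params`.
#' @export
migration_params <- function(forcing_amplitude = 0.1, mesh_spacing = 50,
                             xi = 1, tau = 30, tau_eff = 40) {
  if (forcing_amplitude < 0) {
    stop("migration_params: forcing_amplitude must be >= 0", call. = FALSE)
  }
  if (mesh_spacing <= 0) {
    stop("migration_params: mesh_spacing must be positive", call. = FALSE)
  }
  if (tau <= 0 || tau_eff <= 0) {
    stop("migration_params: tau and tau_eff must be positive", call. = FALSE)
  }
  structure(list(forcing_amplitude = forcing_amplitude,
                 mesh_spacing = mesh_spacing,
                 xi = xi, tau = tau, tau_eff = tau_eff),
            class = "migration_params")
}
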