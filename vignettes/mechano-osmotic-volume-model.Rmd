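---
title: "The mechano-osmotic volume model: assumptions, parameters, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mechano-osmotic volume model: assumptions, parameters, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmovol)
```

## The pump-and-leak model

Animal cells are osmometers held away from Donnan swelling by active ion
pumping. `osmovol`'s core is the three-ion pump-and-leak model (PLM): the
membrane passes water freely and Na, K, Cl through Ohmic conductances
$g_i(V_m - E_i)$ with Nernst potentials $E_i$, while a 3Na-out : 2K-in
electrogenic pump runs at rate `pump_rate` per unit area. Impermeant
osmolytes — an amount $n_X$ with mean negative valence $z_X$ and a neutral
amount $n_Y$ — are trapped in the cell. A steady state must satisfy zero
net flux per ion species, internal electroneutrality, and osmotic balance
with the medium.

`solve_steady_state()` reduces this system: the flux conditions give each
internal concentration in closed form in the membrane potential $V_m$, and
subtracting the osmotic-balance from the electroneutrality condition gives
the water volume $V_w(V_m)$, leaving one scalar root problem solved by
`uniroot` to $10^{-13}$. The residual of all five conditions is checked to
$10^{-8}$ relative; two classical degeneracies are reported as errors
rather than numbers: no impermeant osmolytes (volume undetermined) and a
silent pump (no finite steady volume — the Donnan catastrophe).

The default calibration targets the textbook interior: 145/5/150 mM
Na/K/Cl outside (300 mM), 15/120/65 mM inside (200 mM of ions) plus
100 mM of impermeants at $z_X = -0.7$, at a 2000 µm³ reference volume
with a 0.33 osmotically inactive fraction. `default_ion_params()` derives
$g_{Na}$ and $g_K$ from those targets so the steady state reproduces them
exactly. With this composition all impermeant charge sits on $n_X$ and
$n_Y = 0$; the membrane potential comes out at $-22$ mV, the passive
Donnan value for chloride — this model contains no electrogenic detail
beyond the pump, so it should be read as an osmotic bookkeeping device,
not an excitability model.

Unit system: µm³ / µm² / min / mM / Pa / mV, with the van 't Hoff factor
$RT = 2577$ Pa/mM and thermal voltage 26.71 mV (310 K) fixed internally.

## Osmotic shocks: two timescales

`simulate_osmotic_shock()` integrates the two-timescale response to a
medium exchange. Water flux $dV/dt = L_p A (\Pi_{int} - \Pi_{ext})$
equilibrates within seconds; two permeabilities `Lp_in`/`Lp_out` (defaults
$2\times10^{-5}$ / $1\times10^{-5}$ µm min⁻¹ Pa⁻¹, i.e. a passive
relaxation time of roughly 7–15 s on a 2000 µm³ cell) encode the observed
asymmetry between swelling and shrinking without claiming a mechanism.
The impermeant amounts $n_X$, $n_Y$ never change: fast volume changes
carry water and ions, not dry mass.

Regulation is deliberately phenomenological. In this idealised PLM the
steady-state ion *content* under a rescaled medium equals the passive
post-shock content (concentrations and water volume scale inversely), so
"relax to the new steady state" would predict no recovery at all. What
cells actually do on the minutes scale is move KCl: we therefore relax
the total ion content toward the value that restores the isosmotic water
volume under the current medium, as an electroneutral KCl flux at rate
`k_reg` (default 0.1 min⁻¹), optionally capped at `max_reg_flux` to
reproduce the partial recovery seen after large hypo-osmotic shocks.
Larger shocks produce proportionally larger regulatory fluxes at fixed
`k_reg`, matching the observed shock-size dependence of adaptation.

The stiff water/regulation separation is handled by `deSolve::ode`
(lsoda, rtol = atol = $10^{-9}$), integrating piecewise between protocol
events; requesting output sampling an order of magnitude coarser than the
water-flux timescale is an error, not a silently aliased trace.

With `k_reg = 0` the terminal volume is the passive (Ponder) volume
$V/V_{iso} = R\,(\Pi_{iso}/\Pi) + (1 - R)$ exactly; the affine form, its
slope equal to the osmotically active fraction $R$ and its intercept to
the inactive fraction, is what `ponder_passive_volume()` and
`ponder_regression()` implement. The default inactive fraction 0.33 is
the fitted Ponder intercept convention, applied as a constant excluded
volume $b = 0.33\,V_{iso}$.

## The mechanosensitive extension

Three ingredients couple deformation rate to volume:

1. **Volume follows tension.** Over spreading timescales ion and water
   transport is equilibrated, so a small relative tension change moves
   the steady volume by $d(\delta V/V_{iso}) = \alpha\, d(\delta\gamma/
   \gamma_{iso})$, where the deviation is measured from the growth
   reference $V_{iso}(1 + r_{growth} t)$. `mechanosensitivity_alpha()`
   evaluates $\alpha$ from the full PLM by central finite differences
   (with Richardson step-halving check) when conductances respond to
   tension as $g_i(1 + \beta_i\,\delta\gamma/\gamma_{iso})$. The sign
   structure is the physical content: a tension-activated K leak shrinks
   the cell ($\alpha < 0$), a tension-activated Na leak swells it.

2. **Tension follows area growth.** Membrane tension is a Maxwell fluid
   driven by total-area change,
   $(1 + \tau\,d/dt)\,\delta\gamma/\gamma_{iso} =
   (k\tau/\gamma_{iso})\,dA_{tot}/dt$, with relaxation time $\tau$
   (minutes to tens of minutes when fitted) and areal elastic modulus
   $k$.

3. **Geometry closes the loop.** A spreading cell is a spherical cap, so
   $A_{tot}(V, A_c)$: the cap height is the unique positive root of
   $h^3 + 3a^2h - 6V/\pi = 0$ (solved in closed form via the
   hyperbolic-sine representation, residual-checked at $10^{-12}$ with a
   bisection fallback), and the normalised derivatives
   $f_1 = (1/A_{tot})\,\partial A_{tot}/\partial V$ and
   $f_2 = (1/A_{tot})\,\partial A_{tot}/\partial A_c$ convert volume and
   contact-area rates into relative total-area rate.

Combining 1–3 gives the effective volume dynamics integrated by
`simulate_spreading_volume()`:

$$\tau_{eff}\,\frac{du}{dt} = -u - \xi\tau\,(f_1 V_{iso} r + f_2\,dA_c/dt),
\qquad \tau_{eff} = \tau\,(1 + \xi V_{iso} f_1),$$

with $u = \delta V/V_{iso}$, $\xi = -A_{tot} k\alpha/\gamma_{iso}$ the
dimensionless effective stiffness (positive when tension loses volume),
and growth entering as the constant source $V_{iso}\,r_{growth}$. The
$1/A_{tot}$ normalisation of $f_1, f_2$ is what makes
$\xi V_{iso} f_1$ dimensionless; the $\tau_{eff}$ form is our derivation
from ingredients 1–3 and is the normative model in this package. Its
limits carry the headline physics: $\tau \to \infty$ gives the elastic
law $u = -\xi\,\ln(A_{tot}/A_{tot,0})$; $\tau \to 0$ gives deformation at
constant volume; in the Maxwell-filtered regime $\tau_a \gg \tau$ the
peak loss is proportional to the spreading rate $1/\tau_a$.

Contact area itself is the two-parameter saturating ansatz
$A_c(t) = A_{init} + (A_0 - A_{init})(1 - e^{-t/\tau_a})$. The fitted
observable is the contact area (that is what interference-contrast
imaging measures); the total area is always derived through the cap.
Beyond the hemispherical regime real cells extend lamellipodia, where
the cap is only an approximation — one reason the late-time model trace
should be read qualitatively.

Integration is a semi-implicit trapezoidal scheme (implicit in $u$,
explicit predictor for the geometry), default step 0.1 min, second-order
and robust in the stiff fast-relaxation limit; a step-halving test in the
suite confirms step-size independence at $10^{-5}$. A parameter
combination driving $\tau_{eff} \le 0$ is unphysical and raises an error.

## Fitting pipeline conventions

- **Onset alignment**: time zero is the first sample with detectable
  contact area not exceeding 100 µm²; a cell whose first detected area
  already exceeds the threshold missed its onset and is excluded via a
  classed condition the cohort driver counts — never silently kept.
- **Area fit**: nonlinear least squares with $A_{init}$ pinned to the
  onset value (two free parameters), bounds $A_0 \le 10^4$ µm²,
  $\tau_a \in [0.5, 500]$ min; bound hits are flagged (a linear trace
  legitimately pins $\tau_a$).
- **Volume fit**: $(\xi, \tau)$ by multi-start (4 fixed starts) bounded
  optimisation against the forward simulation, $\xi \in [0, 10]$,
  $\tau \in [0.5, 200]$ min. $V_{iso}$ is the mean of the first three
  volume samples; both data and model are normalised by their own
  first-three-sample mean, making the objective invariant to the
  per-cell absolute calibration offset of exclusion-based volumetry.
  $\xi$ fitting to 0 on a flat trace is a result, not an error. The
  $(\xi, \tau)$ estimates are correlated on single cells — recovery
  simulations show ~6 %/~9 % median error at 1 % noise, but worst-case
  cells are far off; fits on group-averaged traces are the steadier
  choice when comparing conditions, and per-cell fits are what the
  package reports so that heterogeneity stays visible.
- **Fluxes and terciles**: initial $dA/dt$, $dV/dt$ are OLS slopes over
  the first 10 min; terciles split on $dA/dt$ with the remainder cell in
  the middle group (127 cells split 42/43/42) and exact boundary ties
  assigned to the slower group; all estimators are plain OLS throughout,
  no robust variants.
- **Windowed flux CV**: per-10-min OLS slopes of volume; because the
  mean flux of a fluctuating track is near zero, the default normalises
  the slope standard deviation by mean volume per window (the relative
  volume change per window); `method = "plain"` gives std/|mean|. The
  windowed estimator attenuates fluctuation at period comparable to the
  window by the analytic factor $3(\sin x - x\cos x)/x^3$, $x = \omega
  T/2$ — tested against that closed form, and deconvolved in the
  migration driver before model fitting.

## The migration model

A cell crawling at speed $v$ through a fibrous matrix is deformed once
per constriction; we idealise this as sinusoidal area-strain forcing of
amplitude $\varepsilon$ at $\omega = 2\pi v / \ell$ with mesh scale
$\ell$. Filtering through the volume model gives
$$CV(v) = \frac{\xi\,\omega\tau\,\varepsilon}
{\sqrt2\,\sqrt{1 + (\omega\tau_{eff})^2}},$$
zero at rest, monotone in speed, saturating at $\xi\varepsilon\tau/
(\sqrt2\,\tau_{eff})$. Only the lumped pair $(\xi\varepsilon\tau,
\tau_{eff})$ is identifiable from CV-versus-speed data and only that pair
is fitted (`fit_migration_cv`); the defaults $\varepsilon = 0.1$,
$\ell = 50$ µm, $\xi = 1$, $\tau = 30$ min, $\tau_{eff} = 40$ min put the
knee of the transfer function inside the observed 0–2 µm/min speed range
and produce few-percent volume CVs. The mesh scale is the characteristic
distance between successive large deformations along a track — several
cell diameters in a loose collagen network — chosen once as a realistic
study condition; it trades off exactly against $\varepsilon$ and is
therefore never fitted.

## What the synthetic generator does and does not emulate

`generate_spreading_cohort()` draws per-cell $(V_{iso}, \tau_a, A_0,
A_{init})$ — log-normal volumes (CV 0.1), log-normal $\tau_a$ (median
15 min, log-sd 0.5, emulating the observed 15 ± 10 min spreading phase),
plateau areas around 1200 µm² — runs the forward model, and applies
two-level multiplicative log-normal noise: a per-cell scale offset
(CV 0.10, the chamber-to-chamber absolute calibration) and per-sample
noise (CV 0.01, the frame-to-frame accuracy), at 1-min sampling.
Condition presets hold $\xi = 0.15$, $\tau = 15$ min fixed and vary the
spreading timescale (fast 4, control 15, slow 35 min medians), with
$\xi \approx 0$ for the transport-uncoupled preset and a non-spreading
7 %/hr growth preset; the preset constants were fixed once by forward
calibration to the qualitative loss ranges the conditions represent
(~5 %, 10–15 %, 2–3 %, ~0). Per-cell $\tau_a$ and $\xi$ are drawn
independently — the real covariance is unknown.

What is *not* emulated: image-level artefacts, missing frames and manual
gap-filling, cell division or death, the initial volume overshoot some
cell types show, lamellipodial shape beyond the cap, and any correlation
structure in the noise. Passing recovery tests on these cohorts
therefore demonstrates estimator correctness under the stated noise
model, not robustness to everything real microscopy produces.

`generate_shock_experiment()` samples at 100 ms through the passive
phase and 30 s during adaptation, with per-cell resting-volume jitter
(impermeant content scaled with volume so each cell starts at its own
steady state). `generate_migration_tracks()` superimposes the model
response at random phase on measurement noise, grouped at the
0.5 and 1 µm/min speed thresholds.

## Problem sizes and reproducibility

The shipped analyses use cohorts of 15–50 cells (127 for the tercile
bookkeeping), 5 shock magnitudes × 3–5 cells, and 43 migration tracks of
3 h — sizes chosen to match the corresponding single-cell experiments
while keeping every script and the full test suite runnable in minutes
on one core. All stochastic steps take explicit integer seeds and are
bit-reproducible under a fixed seed; every output table carries a
provenance header with package version and seed.

## Known limitations

- Ohmic (linear) flux laws, not Goldman–Hodgkin–Katz; no cotransporters,
  pH or calcium dynamics. Transporter-level interventions enter only
  through parameter changes.
- The pump is a fixed 3:2 stoichiometry with a single rate constant.
- Regulation is a single-rate KCl relaxation with an optional cap — a
  phenomenological stand-in for the RVD/RVI transporter network.
- The spherical cap stops being literal once lamellipodia dominate; the
  millisecond-scale volume loss under mechanical confinement is outside
  the model's validity and deliberately not modelled.
- The Laplace pressure helper returns the standard $2\gamma/r$; the
  order-of-magnitude contractility bound uses a 100 Pa baseline as its
  input constant, and both the $\Pi_{total}$- and exact
  $\Pi/(1-f)$-style variants of the trapped-pressure estimate are
  exposed because the rounding conventions in this regime are loose.
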