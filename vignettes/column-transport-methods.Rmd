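---
title: "Methods: sorption isotherms and two-site nonequilibrium transport in soil columns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sorption isotherms and two-site nonequilibrium transport in soil columns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorbtrans)
```

sorbtrans models the laboratory workflow used to characterize the fate of a
weakly sorbing solute — typically a sulfonamide antibiotic such as
sulfadiazine — in a saturated soil column: batch sorption isotherms, a
conservative-tracer experiment to fix the column hydraulics, a reactive
breakthrough experiment, and inverse estimation of two-site sorption
parameters. This vignette records the models, the numerical choices, and the
design decisions behind the package, including the places where the design
was genuinely open.

## Batch sorption isotherms

A batch experiment shakes a soil mass $m$ (g) with a solution volume $V$
(mL) at initial solute concentration $C_0$ (mg L$^{-1}$) until equilibrium.
The sorbed amount follows from the closed-system mass balance

$$q_e = \frac{(C_0 - C_e)\,V}{m},$$

in mg kg$^{-1}$. Two isotherm laws are supported:

* **Freundlich** $q_e = K_f C_e^{1/n}$, fitted by ordinary least squares of
  $\ln q_e$ on $\ln C_e$ (slope $1/n$, intercept $\ln K_f$);
* **Langmuir** $q_e = q_{max} K_L C_e / (1 + K_L C_e)$, fitted by ordinary
  least squares of $C_e/q_e$ on $C_e$ ($q_{max} = 1/\text{slope}$,
  $K_L = \text{slope}/\text{intercept}$).

The package fits the *linearized* regressions rather than nonlinear least
squares. That choice is deliberate: it is the classical workflow for batch
isotherm data, and it carries an informative failure mode. When the data are
generated by a Freundlich law with $1/n > 1$, the transformed variable
$C_e/q_e \propto C_e^{1-1/n}$ is *decreasing* in $C_e$, the Langmuir
linearization returns a negative slope, the implied $(K_L, q_{max})$ are
non-physical, and `fit_langmuir()` reports `converged = FALSE` (serialized
as the literal `NA` in fit reports). A nonlinear refinement stage could be
added, but it would mask exactly this diagnostic, so it is not the default.

$R^2$ is reported on the transformed scale of each linearization (ln–ln for
Freundlich, $C_e/q_e$ for Langmuir), because that is the scale the
regression is performed on; back-transformed $R^2$ would mix the fit
criterion and the reporting scale. Records with $C_e \le 0$ or $q_e \le 0$ —
which noisy synthetic data can produce — are excluded with a warning rather
than clamped, so the estimator never sees fabricated mass.

The Freundlich exponent classifies the isotherm shape: $1/n < 1$ is an
"L"-type (high-affinity, concave) isotherm, $1/n = 1$ (within $10^{-9}$)
"C"-type constant partitioning, $1/n > 1$ "S"-type.

## Column transport model

Transport in a saturated, homogeneous column of length $L$ is the
one-dimensional convection–dispersion equation (CDE). For a conservative
tracer,

$$\frac{\partial c}{\partial t} =
  D \frac{\partial^2 c}{\partial x^2} - v \frac{\partial c}{\partial x},$$

with pore-water velocity $v$ (cm h$^{-1}$) and hydrodynamic dispersion
coefficient $D = \lambda v + D_0$ (cm$^2$ h$^{-1}$); molecular diffusion
$D_0$ defaults to 0, negligible at typical column flow rates. For linear
equilibrium sorption the solute is retarded by
$r = 1 + \rho K_d/\theta_v$, with bulk density $\rho$ (g cm$^{-3}$) and
volumetric water content $\theta_v$.

Reactive transport uses the two-site conceptualization: a fraction $f$ of
the sorption capacity equilibrates instantaneously (type-1 sites,
$s_1 = f K_d c^{\beta}$), and the remainder approaches equilibrium by
first-order kinetics at rate $\alpha$ (h$^{-1}$):

$$\left(1 + \frac{f \rho K_d \beta c^{\beta-1}}{\theta_v}\right)
  \frac{\partial c}{\partial t} + \frac{\rho}{\theta_v}
  \frac{\partial s_2}{\partial t} =
  D \frac{\partial^2 c}{\partial x^2} - v \frac{\partial c}{\partial x},
  \qquad
  \frac{\partial s_2}{\partial t} =
  \alpha\left[(1-f) K_d c^{\beta} - s_2\right].$$

Two formulation details deserve a note:

* The kinetic equation is written with the rate coefficient $\alpha$
  multiplying the departure from equilibrium, which is the only
  dimensionally consistent first-order form ($\alpha$ in h$^{-1}$, both
  sides in mg kg$^{-1}$ h$^{-1}$).
* For $\beta \neq 1$ the storage coefficient uses the chain-rule derivative
  $\partial s_1/\partial t = f K_d \beta c^{\beta-1}\,\partial c/\partial t$.
  At $c \to 0$ with $\beta < 1$ this derivative diverges; the solver floors
  $c$ at $10^{-10}$ inside the coefficient (equivalently, defines
  $c^{\beta-1} \cdot c \equiv c^{\beta}$) and treats the nonlinearity by
  Picard iteration. $\beta$ defaults to 1 (linear kinetic sorption); it is
  accepted as an input so a batch Freundlich $1/n$ can be propagated, but
  the inverse machinery holds it fixed.

**Boundary and initial conditions.** The inlet is a third-type (flux)
condition $v c_{in} = v c - D\,\partial c/\partial x$ at $x = 0$; the outlet
has zero dispersive gradient; the column starts solute-free. The effluent
concentration is the resident concentration in the outlet cell — under the
zero-gradient outlet this equals the flux concentration leaving the column,
and at the column Peclet numbers of interest ($vL/D \approx 85$) it agrees
with the semi-infinite flux-averaged closed form to better than 0.01. These
are the standard finite-column conventions of inverse-modelling transport
codes.

**Water content.** $\theta_v$ is rarely reported with column datasets. The
default derivation uses the metered flow: Darcy flux
$q = Q/A$ and $\theta_v = q/v$, which for 0.6 mL min$^{-1}$ through a 5 cm
diameter column at $v = 4.370$ cm h$^{-1}$ gives $\theta_v \approx 0.42$
(`theta_from_flow()`). An alternative porosity-from-bulk-density mode
($1 - \rho/2.65 \approx 0.49$ at $\rho = 1.34$) is available
(`porosity_from_bulk_density()`); configuration-driven runs log which
provenance was used, since $K_d$-type parameters are only interpretable
together with it.

## Numerical scheme

The solver is a cell-centered finite-volume discretization (mass-conservative
by construction) with second-order central differences for advection and
dispersion — chosen over first-order upwinding to avoid numerical
dispersion, at the price of the grid Peclet bound $v \Delta x / D \le 2$,
which is enforced with a clear error. For $\lambda = 0.176$ cm this bound
means $\Delta x \le 2\lambda = 0.35$ cm; the default grid uses
`nx = 150` cells over 15 cm ($\Delta x = 0.1$ cm, cell Peclet
$\approx 0.57$).

Time integration is Crank–Nicolson with a fixed step per pulse leg
(default `dt_max = 0.05` h), the step matrices factorized once per leg. The
step count is chosen so the pulse switch falls exactly on a step boundary —
the injected mass is never smeared across the switch. An `"upwind"` scheme
is available for advection-dominated limits (e.g. near-zero dispersivity,
where the central Peclet bound would require an impractical grid); it pairs
first-order upwinding with backward-Euler stepping, which is free of the
ringing Crank–Nicolson exhibits at sharp fronts, at the cost of numerical
smearing of order $v\Delta x/2 + v^2\Delta t/2$.

Verification anchors, all exercised in the test suite:

* agreement with the closed-form erfc solution of the CDE
  (`analytic_cde_btc()`, evaluated on the log scale where the
  $e^{vL/D}$ factor would overflow) to < 0.01 in $C/C_0$;
* exact reduction to the tracer at $K_d = 0$ and to the retarded
  equilibrium CDE at $f = 1$ (the latter checked against the rescaled
  tracer solution, identical equations after mapping
  $v \to v/r$, $D \to D/r$);
* monotone convergence to the equilibrium solution as
  $\alpha \to 100$ h$^{-1}$;
* global mass balance (effluent + stored aqueous + $s_1$ + $s_2$ vs
  injected) to 1% on the default grid and 0.1% at 4-fold refinement;
* grid-refinement changes below 0.005 in $C/C_0$.

All simulations are deterministic; the transport module contains no
randomness.

## Inverse estimation

The inversion mirrors the two-stage practice of column studies: fit
$(v, \lambda)$ to the conservative-tracer curve first, then fit
$(f, K_d, \alpha)$ to the reactive curve with the hydraulics frozen.
Residuals are unweighted differences in $C/C_0$ — the implied objective of
standard breakthrough fitting — minimized by Levenberg–Marquardt
(`minpack.lm::nls.lm`) under box bounds chosen generously around typical
column values: $v \in [0.1, 50]$ cm h$^{-1}$, $\lambda \in [10^{-3}, 10]$
cm, $f \in [0, 1]$, $K_d \in [0, 10]$ L kg$^{-1}$,
$\alpha \in [10^{-5}, 10]$ h$^{-1}$. Estimates that touch a bound raise a
warning flag in the result.

Start points are fixed, documented constants (five per fit; see
`fit_tracer_btc()` and `fit_two_site_btc()`), so fits are reproducible
without any random seed. The best final objective wins; exact ties break to
the smaller $\lambda$ (tracer) or smaller $\alpha$ (two-site). Once a start
attains an essentially exact fit (SSR below `stop_ssr`, default
$10^{-10}$), remaining starts are skipped — they cannot improve the result,
and the outcome is unchanged and still deterministic.

**The time axis of a pore-volume curve.** A breakthrough curve is recorded
against pore volumes, but fitting $v$ requires times. In a real experiment
the duration of one pore volume is known *independently of the fitted
velocity* — from the metered pump flow and the water content — so `btc`
objects carry `hours_per_pv` as metadata and the tracer fit insists on it.
Without it, a pore-volume-domain tracer curve determines only $\lambda$
(the dimensionless curve depends on $L/\lambda$ alone), and $v$ would be
unidentifiable.

**Identifiability.** Two structural degeneracies matter in practice:

* When the optimum sits at $f \ge 0.99$ or $K_d \le 10^{-3}$, the kinetic
  sites carry no signal and $\alpha$ is flagged unidentifiable rather than
  reported naively.
* When $\alpha T \ll 1$ for the experiment duration $T$, the kinetic sites
  barely load and the curve depends on $f$ and $K_d$ essentially only
  through the product $f K_d$ (the instantaneous retardation). Noise-free
  round trips still recover the individual parameters — the global minimum
  is exact — but with even 1% measurement noise the estimates wander along
  the $f K_d$ valley while their product stays put. At
  $\alpha = 0.001$ h$^{-1}$ and $T \approx 27$ h the sites load by ~3%, and
  replicate fits return $f$ anywhere between 0.18 and 1 with $f K_d$ stable
  to 1%. Interpreting fitted $f$ and $K_d$ separately therefore requires
  $\alpha T$ of order 1 — or an honest admission that only $f K_d$ was
  measured.

On noise-free self-generated data the fits reach $R^2 > 0.9999$ and
RMSE $< 10^{-3}$, comfortably inside the $R^2 \ge 0.915$, RMSE $< 0.1$
range typical of real column datasets — the round trips validate the
estimator, not the field applicability of the model.

## Breakthrough-curve metrics

`summarize_btc()` reports breakthrough (first upward crossing of a
threshold, linearly interpolated), elution (last downward crossing), peak
(discrete argmax with parabolic refinement through the three neighbouring
points, applied only at a strict local maximum so plateaus and steps are
not overshot), and mass recovery (trapezoid rule on the native grid — no
smoothing, which is a plotting concern, not a metrics concern).
"Breakthrough" has no universal numeric definition; the default threshold is
$C/C_0 = 0.05$, it is configurable, and every report carries the threshold
used. Curves that never cross the threshold are flagged instead of erroring.

## The synthetic-data generator

The generator emulates the experimental designs the analysis assumes, so the
whole chain is testable without external data:

* **Batch design** — initial concentrations 10–30 mg L$^{-1}$ (five
  levels), 10 mL solution on 5 g soil (water-to-soil 2:1), 25 °C. The
  equilibrium point for each $C_0$ solves
  $C_e + (m/V)q(C_e) = C_0$ by monotone root-finding (bracket $[0, C_0]$,
  tolerance $10^{-10}$), so generated records satisfy the batch mass balance
  to $10^{-8}$ by construction.
* **Column design** — 15 cm × 5 cm column at $\rho = 1.34$ g cm$^{-3}$,
  0.6 mL min$^{-1}$ flow, a 5-PV tracer pulse and a 3-PV reactive pulse,
  effluent resampled at 0.1 PV emulating a fraction collector.
* **Noise** — seeded Gaussian, additive or multiplicative
  (Mersenne–Twister, the seed recorded in all outputs and restored RNG
  state, so generation never disturbs the caller's stream). Suggested
  magnitudes: multiplicative 2% on measured concentrations (HPLC-scale
  error) for isotherms, additive 0.01 on $C/C_0$ for breakthrough curves —
  levels at which fitted goodness-of-fit lands in the 0.92–0.99 $R^2$ range
  familiar from real data.

Isotherm noise is applied to the *measured* $C_e$ and $q_e$ is then
recomputed through the mass balance, exactly as error propagates in a real
batch experiment. This magnifies noise substantially: at the weakly sorbing
conditions above, $q_e = (C_0 - C_e)V/m$ turns a 1% error in $C_e$ into
roughly a 12% error in $q_e$. Consequences worth knowing: fitted $K_f$ has
a convexity bias at moderate noise (about +65% mean bias at 2% Ce noise in
1000-replicate simulations; below 3% at 0.5% noise), and noisy records can
legitimately have $q_e \le 0$ (excluded by the fitters, with a warning).

What the generator does *not* emulate: effluent pH dynamics, metal
speciation and hydroxide precipitation chemistry, desorption hysteresis,
preferential flow, and any temperature dependence. Passing round trips
therefore demonstrate that the estimators invert the stated forward models —
not that those models capture every process in a real soda saline–alkali
wetland soil.

## Known limitations and degenerate regimes

* With a long pulse (≥ 3 PV) and small $\alpha T$, the simulated peak
  necessarily plateaus near $C/C_0 = 1$: dispersion at realistic $\lambda$
  cannot keep a 3-PV plateau below ~0.99, and the kinetic sink removes only
  $\sim \rho\,\alpha (1-f) K_d T/\theta_v$ of the plateau. Observed peaks
  around 0.93 under such parameters imply processes (or effective
  dispersion) beyond this model; the package reproduces the model, not the
  discrepancy.
* The two-site model here is chemical nonequilibrium in a fully mobile
  liquid phase; dual-porosity mobile–immobile water, degradation and 2-D/3-D
  effects are out of scope.
* The nonlinear ($\beta \neq 1$) path uses backward-Euler/Picard stepping
  and is first-order accurate in time; it is intended for forward
  exploration, not inversion.

## Problem sizes of the routine checks

The shipped test suite exercises: 5-point isotherm fits; 150-cell columns
at 0.05 h steps over 8 PV; 1000-replicate isotherm Monte-Carlo
(unbiasedness at small noise); a 5-replicate seeded noisy
breakthrough-recovery study run with a reduced 2-point multistart; and
single noise-free round trips for each published treatment parameter set.
These sizes were chosen to give each property a meaningful sample while
keeping a full run on one CPU in minutes.
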