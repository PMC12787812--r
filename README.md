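# sorbtrans

Sorption isotherms and two-site nonequilibrium solute transport in
saturated soil columns.

## What this is for

Laboratory studies of contaminant fate in soil — antibiotics such as
sulfadiazine, trace organics, or any weakly sorbing solute — typically
combine three experiments: batch equilibrium sorption, a conservative-tracer
(e.g. Br⁻) column run to characterize hydraulics, and a reactive
breakthrough run to characterize transport. sorbtrans implements the full
modelling chain for that workflow, for researchers who want the fitting and
simulation steps scripted, tested and reproducible rather than clicked
through a GUI:

* **Isotherms** — sorbed amounts from the batch mass balance
  `qe = (C0 − Ce)·V/m`; Freundlich (`qe = Kf·Ce^(1/n)`) and Langmuir
  (`qe = qmax·KL·Ce/(1 + KL·Ce)`) fits by the classical linearized
  regressions, including the diagnostic non-convergence (`NA`) of the
  Langmuir linearization on super-linear data, and L/C/S shape
  classification by `1/n`.
* **Forward transport** — a finite-volume convection–dispersion solver
  (`∂c/∂t = D ∂²c/∂x² − v ∂c/∂x`, retardation `r = 1 + ρKd/θv`) with
  two-site equilibrium/kinetic sorption
  (`s1 = f·Kd·c^β`, `∂s2/∂t = α[(1−f)·Kd·c^β − s2]`), third-type inlet,
  finite pulses, and built-in mass-balance accounting; plus the closed-form
  erfc solution of the CDE as an independent cross-check.
* **Inverse estimation** — deterministic multistart bounded
  Levenberg–Marquardt fits of `(v, λ)` from tracer curves and
  `(f, Kd, α)` from reactive curves (hydraulics frozen, the standard
  two-stage procedure), with R²/RMSE goodness metrics, bound-hit warnings
  and identifiability flags.
* **Breakthrough metrics** — breakthrough/elution pore volumes at a stated
  threshold, peak position and height, trapezoid mass recovery, and
  curve-to-curve comparisons.
* **Synthetic data** — a seeded generator emulating the batch design
  (10–30 mg/L on 5 g soil in 10 mL) and the column design (15 cm × 5 cm,
  1.34 g/cm³, 0.6 mL/min, 5-PV tracer and 3-PV solute pulses, 0.1-PV
  fraction sampling), so every estimator can be validated by round trip.
* **Reproducible runs** — YAML-configured modes (`simulate`, `fit-isotherm`,
  `fit-tracer`, `fit-btc`, `generate`, `summarize`) via `run_config()`, each
  writing its outputs, a resolved config and a log; a thin CLI wrapper
  lives in `inst/scripts/sorbtrans.R`.

See the vignette in `vignettes/column-transport-methods.Rmd` for the models,
numerical scheme, identifiability caveats and design decisions.

## Worked example

Generate a noisy batch isotherm from known Freundlich parameters and refit
it:

```r
library(sorbtrans)

design  <- batch_design()                       # 10-30 mg/L, 10 mL on 5 g
truth   <- freundlich_params(kf = 0.181, inv_n = 0.952)
records <- gen_isotherm_dataset(design, truth,
             noise_model("multiplicative_gaussian", sd = 0.005, seed = 42))
fit_freundlich(records)
#> Freundlich isotherm fit (linearized ln-ln regression)
#>   Kf   = 0.1616 (mg/kg)(L/mg)^(1/n)
#>   1/n  = 0.9808  [L-type isotherm]
#>   R2   = 0.9887 (ln-ln scale), n = 5
```

Even 0.5% measurement noise on `Ce` moves `Kf` from 0.181 to 0.162: the
batch mass balance magnifies concentration error roughly 12-fold into `qe`
at these weakly sorbing conditions (see the vignette).

Simulate a reactive breakthrough curve and recover its parameters:

```r
column <- soil_column(length_cm = 15, diameter_cm = 5,
                      bulk_density = 1.34, theta = 0.42)
hyd    <- hydraulics(v = 4.370, dispersivity = 0.176)   # D = 0.769 cm2/h
sorb   <- two_site_sorption(f = 0.292, kd = 0.205, alpha = 0.027)
pulse  <- pulse_schedule(c_in = 1, pulse_pv = 3, total_pv = 8)

sim <- simulate_two_site(column, hyd, sorb, pulse)
summarize_btc(sim)
#> Breakthrough-curve summary (threshold C/C0 = 0.05 )
#>   breakthrough: 0.9179 PV
#>   peak:         C/C0 = 0.9662 at 3.651 PV
#>   elution:      4.526 PV
#>   mass recovery: 2.922 PV

obs <- gen_btc(column, hyd, sorb, pulse)        # 0.1-PV sampling, no noise
fit_two_site_btc(obs, column, hyd, pulse)
#> Breakthrough-curve fit (two-site sorption)
#>   f        = 0.292
#>   kd       = 0.205
#>   alpha    = 0.027
#>   R2 = 1, RMSE = 6.157e-15, iterations = 9, converged = TRUE
```

The solute breaks through at 0.92 PV, peaks at C/C0 = 0.966, and 2.92 of
the 3 injected pore-volume-equivalents are recovered in the effluent (the
rest is still sorbed at the kinetic sites). The noise-free round trip
returns the generating parameters to machine precision.

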