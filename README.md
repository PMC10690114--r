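# petkin

Quantification chain for dynamic brain PET studies of reversibly binding
radiotracers, written for imaging scientists and pharmacometricians who need
the full path from regional time–activity curves to drug-occupancy and
concentration–occupancy estimates — with a seeded synthetic-data generator so
the whole chain is testable without access to clinical scan data.

## What it computes

Given regional time–activity curves (TACs) and a metabolite-corrected
arterial input function (AIF) `C_p`:

- **Compartment models.** One- and two-tissue compartment fits by weighted
  nonlinear least squares, with the total volume of distribution
  `V_T = (K1/k2)(1 + k3/k4)`, AIC-based model comparison
  (`AIC = n ln(RSS/n) + 2k`), and the indirect binding potential
  `BP_ND = (V_T − V_ND)/V_ND`.
- **Graphical / reference-tissue methods.** Logan analysis (slope = `V_T`
  past the `t* = 30` min equilibration cutoff), its noninvasive
  reference-region variant (slope = DVR, `BP_ND = DVR − 1`), and the
  simplified reference tissue model solved by basis-function expansion,
  which also supplies the reference efflux constant `k2′`.
- **Reliability.** Test–retest variability
  `TRT(%) = 100 (test − retest) / [(test + retest)/2]`, the one-way
  intraclass correlation `(BMS − WMS)/(BMS + WMS)`, and time-stability of
  `V_T` under truncated acquisitions.
- **Occupancy.** Lassen plots
  (`V_T_base − V_T_block = occ · (V_T_base − V_ND)`; slope = global
  occupancy, x-intercept = `V_ND`), the injected-dose-weighted surrogate AIF
  for a blocking scan without arterial sampling, and regional occupancies
  `100 (1 − BP_ND_block / BP_ND_base)`.
- **PK-PD.** An effect-site link `dCe/dt = ke0 (Cp − Ce)` solved exactly for
  piecewise-linear plasma input, and the sigmoidal Emax model
  `Occ(%) = Emax C^γ / (EC50^γ + C^γ)` with `Emax` fixed at 100% — fitted in
  plasma mode (`γ = 1`) or effect-site mode (`γ` free), including a joint
  `(ke0, EC50, γ)` fit to timestamped peak/trough occupancy observations.

`run_pipeline()` chains simulate → fit → occupancy/reliability → PK-PD from
one (YAML or list) configuration with a single seed and hash-stamped output
tables.

## Worked example

```r
library(petkin)

aif    <- simulate_aif()                 # bolus AIF, peak 52 kBq/mL at 1.5 min
frames <- default_frame_schedule()       # 34 frames, 30-min break, ends 245 min
truth  <- default_ground_truth()         # 12 regions, shared V_ND = 1.5 mL/cm^3

noisy <- add_noise(simulate_tac(truth$putamen, aif, frames), 0.05, seed = 1)
fit_2tc(noisy, aif)
#> <kinetic_fit> 2TC: V_T = 13.525 mL/cm^3, AIC = 12.45
#>    K1 = 0.3072 (SE 0.025), k2 = 0.2046 (SE 0.049), k3 = 0.1577 (SE 0.023), k4 = 0.01969 (SE 0.0012)

logan_vt(noisy, aif)
#> <graphical_fit> V_T = 13.491 (t* = 30 min, 19 points, r^2 = 0.9999)
```

The putamen's true `V_T` is 13.5 mL/cm³: both routes recover it, the 2TC fit
returning the rate constants (truth: 0.30, 0.20, 0.16, 0.02) and the Logan
slope sitting marginally lower, as graphical methods do under noise.

```r
vb <- vapply(truth, function(tr) tr$vt, numeric(1))   # baseline V_T per region
vk <- 1.5 + (1 - 0.7) * (vb - 1.5)                    # 70%-blocked V_T
lassen(vb, vk)
#> <occupancy_fit> occupancy = 70.0% (SE 0.00), V_ND = 1.500 mL/cm^3, 12 regions

cohort <- simulate_pkpd_cohort(doses_mg = c(50, 100, 200, 300, 600, 600),
                               ke0 = 0.3, ec50 = 5.52, gamma = 0.758,
                               noise_sd = 2, seed = 2)
fit_emax_effect_site_joint(cohort)
#> <emax_fit> mode effect_site: EC50 = 5.674 ng/mL, gamma = 0.813, ke0 = 0.301 /h (Emax fixed 100%)
```

The Lassen slope returns the programmed 70% occupancy with the shared
nondisplaceable volume at its x-intercept, and the joint effect-site fit
recovers the generating `(ke0, EC50, γ)` from two occupancy observations per
subject (2 h peak, 24 h trough) to within a few percent at 2% occupancy
noise.

See `vignettes/petkin-methods.Rmd` for the models, conventions, and the
generator's scope.

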