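---
title: "Models and methods behind petkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind petkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkin)
```

petkin implements the quantification chain used in clinical characterization
studies of reversibly binding brain PET radiotracers: compartmental and
graphical kinetic modeling of regional time–activity curves (TACs) against a
metabolite-corrected arterial input function (AIF), test–retest reliability
summaries, Lassen-plot estimation of drug occupancy, and a sigmoidal Emax
model linking drug concentration to occupancy through an effect-site
compartment. Because raw clinical PET data are rarely redistributable, the
package ships a seeded synthetic-data generator whose outputs have known
kinetic ground truth, so every estimator can be validated end to end.

## Compartment models

Tissue concentration is modeled by the serial two-tissue compartment (2TC)
system

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3) C_1 + k_4 C_2, \qquad
  \frac{dC_2}{dt} = k_3 C_1 - k_4 C_2,$$

with $C_T = C_1 + C_2$ and the metabolite-corrected plasma concentration
$C_p$ as input. Setting $k_3 = 0$ gives the one-tissue (1TC) model. The
macro-parameter of interest is the total volume of distribution,
$V_T = (K_1/k_2)(1 + k_3/k_4)$ (1TC: $K_1/k_2$), and the nondisplaceable
binding potential follows indirectly as
$\mathrm{BP_{ND}} = (V_T - V_{ND})/V_{ND}$.

The model curve is computed as the closed-form impulse response convolved
with the linearly interpolated AIF on a fine uniform grid, then averaged
over each scan frame. The grid step is 0.1 min during fitting and 0.05 min
in the generator; frame averages use an 8-fold spline-refined trapezoid
because the tissue curve is strongly convex inside the short early frames.
With these choices the forward model agrees with an independent stiff-ODE
solution to better than 0.05%, and the small grid mismatch between
generator and fitter guards against the trivial "inverse crime" of fitting
with the exact forward operator that produced the data.

Fitting is weighted nonlinear least squares (`minpack.lm`), weights equal to
frame duration by default (uniform variance per unit scan time), rates
bounded in $[10^{-4}, 10]$ with deterministic starts
($K_1 = k_2 = 0.1$, $k_3 = k_4 = 0.01$) and a log-spaced multi-start ladder
used only when the first start fails. Standard errors come from the
Gauss-Newton covariance. Model comparison uses
$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2k$ without small-sample correction.
A fit with $k_4$ pinned at its lower bound is flagged as irreversible-like
rather than silently accepted. No fractional blood-volume term is included;
delay/dispersion correction of the AIF is likewise not modeled.

## Graphical and reference-tissue methods

Logan graphical analysis regresses
$\int_0^t C_T / C_T(t)$ on $\int_0^t C_p / C_T(t)$ over frames whose
midpoint is at or past the equilibration cutoff $t^\* = 30$ min; the slope
estimates $V_T$. Conventions that the literature leaves open are fixed and
documented here: frame midpoints are the reference times, the tissue
integral is a midpoint trapezoid with a leading half-triangle from the
origin, the plasma integral is a trapezoid on the AIF's own sampling grid,
and the regression is ordinary least squares (y-errors only). Logan
estimates carry a small negative bias for slowly equilibrating regions at
$t^\* = 30$ — visible in the package's own identity-line checks and a
well-known property of the method under noise — which is why the noiseless
Lassen round-trip validation quantifies $V_T$ with the 2TC fit instead.

The simplified reference tissue model (SRTM),
$C_T = R_1 C_{ref} + \left(k_2 - \tfrac{R_1 k_2}{1+\mathrm{BP_{ND}}}\right)
C_{ref} \otimes e^{-k_2 t/(1+\mathrm{BP_{ND}})}$,
is solved by basis-function expansion: 100 log-spaced candidate exponential
rates in $[10^{-3}, 1]\,\mathrm{min}^{-1}$, a weighted linear sub-fit per
basis, then a local univariate refinement — deterministic and free of
starting-value sensitivity. The reference efflux constant $k_2' = k_2/R_1$
feeds the noninvasive Logan variant (slope = DVR,
$\mathrm{BP_{ND}} = \mathrm{DVR} - 1$). $k_2'$ is taken from an SRTM fit to
the putamen, the highest-signal region; if no putamen TAC is present the
highest-uptake region is used with a warning.

## Occupancy analysis

For a blocking study the Lassen plot regresses
$V_T^{base} - V_T^{block}$ on $V_T^{base}$ across regions; the slope is the
global fractional occupancy and the x-intercept is $V_{ND}$, assumed shared
across regions. OLS is used (the choice of orthogonal vs ordinary
regression is immaterial at the noise levels validated here); all regions
present in both scans enter unweighted. A slope below $10^{-6}$ yields an
"occupancy ≈ 0" result with $V_{ND}$ flagged indeterminate rather than a
wild intercept — mirroring low-dose scans in practice where neither
BP~ND~ nor regional occupancies can be derived.

When arterial sampling is only available for the baseline and first
blocking scans, the second blocking scan's AIF is the injected-dose-weighted
surrogate
$\mathrm{AIF}_{b2} = \mathrm{ID}_{b2}\left(\mathrm{AIF}_{base}/\mathrm{ID}_{base}
+ \mathrm{AIF}_{b1}/\mathrm{ID}_{b1}\right)/2$. Regional occupancies use the
BP~ND~ ratio, $100\,(1 - \mathrm{BP_{ND}^{block}}/\mathrm{BP_{ND}^{base}})$,
with $V_{ND}$ sourced from the highest-occupancy (first blocking) scan.
Out-of-range occupancies under noise are passed through with a warning, not
clipped.

## Reliability

Test–retest variability is
$\mathrm{TRT}(\%) = 100\,(test - retest)/[(test + retest)/2]$ (signed;
summaries take absolute values), and reliability is the one-way ICC,
$(\mathrm{BMS} - \mathrm{WMS})/(\mathrm{BMS} + \mathrm{WMS})$. A
zero-total-variance cohort raises an error rather than returning 1 — a
silent default there would hide degenerate simulations. Time stability
refits a quantifier on truncated data and reports signed percent bias
against the full-duration estimate; truncations below a method's minimum
frame count are marked unavailable.

## Concentration–occupancy (PK-PD) link

Plasma kinetics follow the oral one-compartment closed form; the effect-site
concentration solves $dC_e/dt = k_{e0}(C_p - C_e)$ by an exact
piecewise-linear update (no step-size error beyond the linearity
assumption). Occupancy follows the sigmoidal Emax model
$\mathrm{Occ}(\%) = E_{max} C^{\gamma}/(EC_{50}^{\gamma} + C^{\gamma})$ with
$E_{max}$ fixed at 100%. Internally $E_{max}$ is a fraction with outputs in
percent, so $C = EC_{50}$ returns exactly 50% for any $\gamma$ — the
defining property of a half-maximal concentration. In plasma mode $\gamma$
is fixed at 1 (noncooperative binding); in effect-site mode $\gamma$ is
free. The joint fit estimates $(k_{e0}, EC_{50}, \gamma)$ from timestamped
occupancy observations (e.g. a 2 h peak and 24 h trough scan per subject)
by unweighted least squares on occupancy percent, with $k_{e0}$ searched on
the log scale from a deterministic 7-point grid spanning
$[10^{-3}, 10^2]\ \mathrm{h}^{-1}$. Occupancy observations from a single
post-dose time leave $k_{e0}$ unidentifiable and are flagged. All kinetic
modules work in minutes post-injection and the PK-PD module in hours
post-dose; conversions pass through `minutes_to_hours()`/
`hours_to_minutes()` so the unit bridge is explicit.

## What the synthetic data emulate — and what they do not

The generator reproduces, by construction: a bolus AIF (linear rise to a
peak at 1.5 min, 52 kBq/mL, tri-exponential decay with fractions
0.85/0.12/0.03 at 0.5/0.05/0.004 min⁻¹); a parent fraction falling to ~27%
at 60 min and plateauing at 25%; twelve gray-matter regions sharing
$V_{ND} = K_1/k_2 = 1.5$ mL/cm³ with $V_T$ graded from ~5 to 13.5 mL/cm³;
a putamen SUV peak of ~8 near 30 min; a cerebellum with $V_T = 6.4$ mL/cm³
peaking before 5 min with much faster washout; frame noise with standard
deviation `noise_level * activity / sqrt(duration)`, truncated at zero
(a small positive bias at extreme noise is the documented price); a
245-min frame schedule with a 30-min mid-scan break; blocking scans built
by rescaling $k_3 \to k_3(1-\omega)$ so the blocked
$V_T = V_{ND} + (1-\omega)(V_T - V_{ND})$ exactly, with a shared
condition-invariant $V_{ND}$ as the Lassen model assumes; and injected
doses drawn per scan with the AIF scaling proportionally, so the weighted
surrogate AIF is exact for the simulated third scan.

Test–retest cohorts use log-normal between-subject multipliers on $K_1$ and
$k_3$ (CV 15%) plus two within-subject sources: frame counting noise and a
scan-level log-normal $K_1$ multiplier (CV 7%). The scan-level term exists
because counting noise alone, averaged over a multi-hour acquisition,
produces test–retest spreads of well under 1% — an order of magnitude below
what outcome-measure reliability studies report; day-to-day physiology and
input-function measurement error, which act multiplicatively at the scan
level, dominate in practice. With these defaults the putamen Logan $V_T$
shows a mean absolute TRT of ~5% and ICC ~0.84.

Not emulated: image-domain effects (partial volume, motion, reconstruction
noise correlations between regions), metabolism differences across
conditions, AIF measurement error as a separate channel, and nonlinear
drug clearance. The PK generator is deliberately a linear one-compartment
oral model, so while occupancy is dose- and time-dependent (about 60–91%
at 2 h and 31–75% at 24 h across 50–600 mg under the defaults), it cannot
reproduce the very low troughs that strongly nonlinear clearance produces
at low doses. Passing tests therefore certify the estimators against the
stated kinetic models — not against every artifact of real data.

## Numerical choices and degenerate inputs

- Convolution: trapezoid-corrected FFT on a uniform grid; frame averages by
  spline-refined trapezoid. Problem sizes in the test-suite simulations
  (e.g. 100-replicate AIC selection, 6-region Lassen sweeps at five
  occupancy levels, 100-replicate EC50/γ recovery) were chosen so each
  property exercises genuine Monte-Carlo variability while the whole suite
  stays desk-scale.
- All-zero TACs, sub-minimum frame counts, non-covering AIFs, zero tissue
  activity at qualifying Logan frames (dropped with a warning), degenerate
  ICC cohorts, all-zero occupancies, and single-concentration Emax designs
  are each rejected or flagged explicitly rather than producing silent
  numbers.
- Stochastic outputs are reproducible bit for bit under a fixed seed, and
  seeded helpers restore the global RNG state on exit.
- Missing plasma free fraction defaults to 1 with a warning; none of the
  computed outcome measures divide by it.

## Known limitations

SRTM applied to targets that are genuinely two-tissue underestimates
BP~ND~ relative to the 2TC/indirect route (the familiar ~15% compression is
visible here too); Logan at $t^\* = 30$ min carries a small negative $V_T$
bias for slowly equilibrating regions; the Emax fit treats occupancy
residuals as homoscedastic in percent; and the pipeline's report stage is a
plain-text summary, not a figure-generating layer.
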