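---
title: "Plate-based DLS screening of the diffusion interaction parameter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plate-based DLS screening of the diffusion interaction parameter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platekd)
```

## The measurement and its model

Dynamic light scattering (DLS) measures the intensity autocorrelation
function (ACF) of scattered laser light. For a monodisperse dispersion
the ACF decays as

$$ g_2(\tau) - 1 = \beta\, e^{-2 \Gamma \tau}, \qquad
   \Gamma = D q^2, \qquad q = \frac{4 \pi n}{\lambda} \sin(\theta / 2), $$

so the decay rate gives the mutual diffusion coefficient $D$, and the
Stokes–Einstein relation $R_H = k_B T / (6 \pi \eta D)$ converts it to a
hydrodynamic radius. At finite protein concentration $c$, $D$ depends
linearly on $c$ to first order:

$$ D = D_0 (1 + k_D c), $$

and the slope-over-intercept coefficient $k_D$ (mL/g, with $c$ in g/mL)
is the *diffusion interaction parameter*: positive $k_D$ indicates net
repulsive protein–protein interactions (colloidal stability), negative
$k_D$ net attraction (aggregation propensity). Plate readers measure a
dilution series per formulation in a 384-well plate, wells are read
sequentially, and $k_D$ is obtained from an ordinary linear fit of $D$
against $c$. This package implements that pipeline end to end —
including a forward simulator of the plate run, because the measured
quantities are perturbed in structured ways (well position, elapsed
time, outliers) that the analysis must be robust to.

## What the simulator emulates

`simulate_plate()` composes, per well:

1. **Acquisition schedule.** Wells are read sequentially (row-major by
   default, matching a first well in the upper row and a last well in
   the bottom row; column-major is available). The per-well dwell
   defaults to 75 s, chosen so the two recommended designs complete in
   5 h (240 wells) and 6.25 h (300 wells). The nominal per-well protocol
   (15 acquisitions of 15 s = 225 s) would give considerably longer
   totals; real instruments interleave auto-attenuation and skip idle
   time, so end times are not reconcilable with the nominal protocol and
   the dwell is an explicit configuration scalar.
2. **Evaporation.** Open wells lose solvent while the plate sits in the
   reader. We model fractional volume loss as linear in time,
   $V(t)/V_0 = \max(f_{\min},\, 1 - r\, m\, e^{-c_0 / s}\, t)$, with a
   base rate $r$ per hour, an edge multiplier $m \ge 1$ (perimeter wells
   evaporate faster), and exponential suppression with the initial
   concentration $c_0$ (scale $s$; concentrated samples are more viscous
   and hold their water). Solute mass is conserved exactly, so the
   effective concentration rises as $c(t) = c_0 V_0 / V(t)$ until the
   volume floor $f_{\min}$ (default 1/6: a 30 µL fill never drops below
   the 5 µL minimum working volume). The defaults
   ($r = 0.0286$ h⁻¹, $m = 2$, $s = 4$ mg/mL) were calibrated
   analytically so that a dilute 2 mg/mL centre well measured at the end
   of a full-plate run shows a 2.5% apparent increase of $D$; the same
   defaults then give ~0.9% at 10 mg/mL and ~0.4% at 14 mg/mL. The
   observed concentration dependence is steeper than a single
   exponential suppression can reproduce, so only the dilute-well drift
   is matched quantitatively and the ordering qualitatively.
3. **ACF noise.** Gaussian per-lag noise with standard deviation
   `noise_sigma0 / sqrt(n_acquisitions)` on a 64-point logarithmic lag
   grid (1 µs–1 s). The default `noise_sigma0 = 0.01` (per-lag s.d.
   ≈ 0.26% of the intercept after averaging 15 acquisitions) represents
   instrument-limited precision: ACFs look like the "smooth
   exponentials" a well-run plate produces, and a second particle
   population at ~10% intensity remains resolvable by the regularised
   inversion, as it was in the experiments this package models. The flat
   per-lag noise model is a simplification — real multi-tau correlators
   have lag-dependent noise — and replicate-to-replicate scatter from
   pipetting and concentration errors is *not* emulated, so
   replicate CVs of $D$ from the simulator are smaller than
   experimental ones. Passing tests therefore demonstrate correctness
   of the estimators under the modelled noise, not full experimental
   variability.
4. **Anomalies.** With configurable probability a well receives a second
   particle population (field-amplitude mixture of two exponentials;
   radius drawn from Normal(42.8, 7.9²) nm at 11.6% intensity by
   default, matching the soluble-aggregate population reported in the
   study this package operationalises), and/or a gross outlier (dust,
   bubbles): a multiplicative displacement of $D$.

The instrument defaults (λ = 830 nm, θ = 158°, n = 1.331, T = 298.15 K,
η = 0.8872 mPa·s) describe a backscatter plate reader with aqueous
solvent at 25 °C; all of them are configuration, none is hard-coded in
the physics. Viscosity enters only through Stokes–Einstein; an explicit
η(c) in the ACF synthesis is deliberately out of scope (a linear hook
can be emulated by adjusting `viscosity_mPas`).

## ACF analysis

`cumulant_fit()` fits the second-order cumulant expansion
$\ln(g_2 - \text{baseline}) = \ln\beta - 2\Gamma\tau + \mu_2 \tau^2$ by
weighted least squares. The baseline is the mean of the trailing quarter
of lags. The fit window keeps the contiguous run of lags whose
baseline-corrected signal exceeds 5% of a crude two-pass intercept
estimate — a rule chosen to keep the log transform away from
noise-dominated lags; weights follow the delta method (∝ signal²). The
polydispersity index is $\mu_2/\Gamma^2$ (clamped at 0). Quality flags
mirror common plate-reader acceptance rules: baseline outside
[0.997, 1.003], SOS ≥ 20, PDI > 0.3. SOS — the proprietary sum-of-squares
metric of plate-reader software — is defined here as the residual sum of
squares over the fit window normalised by the tail-estimated noise
variance; its expectation for a good fit is roughly the window size
minus three, so the default threshold of 20 accepts clean wells with
margin and single wells fluctuate around ~15.

`regularized_distribution()` inverts the ACF on a 60-point logarithmic
radius grid (0.5–500 nm) by non-negative least squares on
$\sqrt{g_2 - \text{baseline}}$ with Tikhonov regularisation
(`reg_weight = 0.005`). Three numerical choices matter and are worth
stating:

* **Tail censoring.** $\sqrt{\max(y, 0)}$ of pure baseline noise has a
  positive half-normal mean, which an unconstrained inversion converts
  into spurious slow modes at the top of the radius grid. Lags past the
  last pair of consecutive excursions above 2 tail-noise s.d. are set to
  zero: isolated spikes do not extend the signal window, coherent
  low-amplitude plateaus (real second populations) do.
* **Heteroscedastic weights.** The noise of $\sqrt{y}$ scales as
  $1/\sqrt{y}$, so short lags are intrinsically better determined; rows
  are weighted accordingly, with the ratio clipped at 5 so the slow-mode
  rows are not drowned.
* **Peak segmentation.** Peaks are contiguous weight regions above a
  threshold; regions separated by ≤ 2 empty grid points are merged
  (noise can zero individual weights inside a broad lobe), and peaks
  below 1% intensity are discarded. Intensity fractions are reported in
  scattered-intensity space without Mie or volume corrections.

The reference software's exact regularisation settings are unknown;
equivalence is claimed at the level of peak positions and intensity
fractions, not full distributions. `analyze_plate()` runs the cumulant
fit per well and triggers the regularised cross-check automatically when
PDI exceeds 0.1 — clean simulated wells sit near PDI 0, a ~10%-intensity
second population lifts the estimate above ~0.12, and a false trigger
merely runs the cross-check, which then finds a single peak.

## Outlier screening and the k_D fit

`grubbs_screen()` applies the two-sided single-outlier Grubbs (extreme
studentized deviate) test, $G = \max_i |x_i - \bar x| / s$ against
$G_{crit} = \frac{n-1}{\sqrt n} \sqrt{t^2/(n - 2 + t^2)}$ with $t$ the
upper $\alpha/2n$ t-quantile, iterated up to `max_removals = 2` per
replicate group. Screening is applied per concentration group — the
replicate structure of the dilution series — rather than to pooled
residuals; a Kolmogorov–Smirnov normality check per group is reported
alongside. Zero-variance groups and groups below n = 3 pass through
untested. `fit_kd()` then fits $D = a + b c$ by unweighted OLS (a
weighted option exists) and reports $D_0 = a$, $k_D = b/a$, $R^2$ and
the excluded points. Concentrations are mg/mL at every interface and
converted to g/mL internally, so $k_D$ comes out in mL/g.

A deliberately unscreened "raw" fit is always available (omit the
`keep` mask) because quantifying what screening buys — the $R^2$
improvement — is part of the method.

## Variability statistics

`pooled_intra_cv()` computes the intra-plate CV as the pooled
within-group standard deviation over the grand mean of the contributing
values (the "overall mean" is not defined more precisely by the source
method description, so the grand mean of pooled values is used and
`average_intra_cv()` additionally reports the mean of per-run CVs — both
orders of averaging are available). One-way and repeated-measures ANOVA
use the standard decompositions via `lm()`, report $F_{crit}$ at
α = 0.05 and apply the double significance rule ($F > F_{crit}$ and
$p \le α$). Post-hoc pairwise pooled-variance t-tests are
Bonferroni-adjusted by default — the correction method the study era
plausibly used; it is configurable. `span_kd()` defaults to
$100 (\max - \min)/|\min|$, which reproduces the reported 39.2% total
span of the acetate k_D set to within rounding of the printed extremes
(39.0%); the phosphate span (37.6% from −14.1 and −15.8 mL/g) is not
reproducible under any of the three candidate definitions, so the
definition used is always echoed in the output and alternatives are
selectable.

## Plate designs

`recommended_design()` generates the two screening designs: *low risk*
(8 formulations × 5 concentrations × 6 vertical replicates = 240 wells,
first well B3, 43.2 mg API at 30 µL/well) and *high quantity* (20 × 3 ×
5 = 300 wells, first well B2, 51.0 mg). Both exclude the 76 edge wells,
put low concentrations on upper rows (they are measured earlier and
evaporate fastest), and pass `validate_layout()` with zero findings.
Two packing details are this package's own interpretation, because the
published captions underdetermine them: (i) the high-quantity design
needs three five-row concentration bands (15 rows) but only 14 non-edge
rows exist, so the fifth replicate of the 10 mg/mL series lives in two
spare upper-row columns; (ii) the printed API budgets (44 mg / 50 mg)
differ from the exact arithmetic (43.2 mg / 51.0 mg) by rounding, and
`api_budget()` always reports the exact value. The 3-step concentration
series of the high-quantity design also sets the default
`min_conc_steps = 3` in `validate_layout()`; 4 steps remain the
recommended practice for new designs and the threshold is configurable.

`builtin_layout()` encodes the experimental layouts (lysozyme intra-
and inter-plate studies) and the A–H well-grouping approaches used to
compare k_D-calculation strategies. The published record fixes the
grouping *sizes* (e.g. approach B: 2 fits × 120 points; C: 64/64/56/56)
and their edge/centre character, but not individual wells — indeed the
stated edge groupings of approach C need more wells than the 76-well
perimeter holds — so wells are packed deterministically along a
two-ring perimeter band (edge-flavoured groups) or in centre blocks,
and the encodings are documented as interpretations. Group membership
is exposed via the `kd_groups` attribute and flows through
`estimate_kd()` and `monte_carlo_design_eval()`.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to what
the checks need: 500 simulated plates for the k_D-recovery error, 200
plates per layout for the edge-vs-centre comparison, 10,000 random
datasets for the Grubbs cross-check, 1,000 for the arithmetic oracles
and the outlier-exclusion property. Every stochastic component takes an
explicit seed, per-simulation seeds are derived deterministically from
the master seed, and identical inputs plus seed give bit-identical
outputs (including written files).

## Known limitations

* The evaporation model is phenomenological (linear loss, exponential
  suppression); it reproduces the dilute-well drift and the
  edge/centre and time orderings, not absolute volumes.
* No pipetting/concentration error term: simulated replicate CVs of
  $D$ are instrument-limited and smaller than experimental ones.
* Laser auto-attenuation, multiple scattering, Marangoni/capillary
  flow physics and number-/volume-weighted distributions are out of
  scope.
* 96- and 1536-well geometries are not supported.
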