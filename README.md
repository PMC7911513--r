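# platekd

High-throughput formulation screening of protein and peptide drugs
leans on plate-reader dynamic light scattering (DLS): a 384-well plate
holds dilution series of many candidate formulations, the reader
measures an intensity autocorrelation function (ACF) per well, and each
formulation's colloidal stability is summarised by the diffusion
interaction parameter *k*<sub>D</sub> from

> *D* = *D*₀ (1 + *k*<sub>D</sub> *c*),

the linear concentration dependence of the mutual diffusion coefficient
(*k*<sub>D</sub> in mL/g; positive = net repulsive protein–protein
interactions, negative = aggregation-prone). The catch is that
plate-based measurements carry structured errors — edge wells evaporate
faster, bottom rows are measured hours after the first well, occasional
wells contain dust or soluble aggregates — and these propagate into
*k*<sub>D</sub> in ways that depend on where the replicates sit on the
plate.

`platekd` is an R package for scientists who design and analyse such
screens. It provides:

* **Plate model** — well addressing (A1–P24), edge/centre and row-band
  classification, acquisition schedules, layout validation against
  screening design rules, plate-map CSV I/O.
* **Forward simulator** — synthetic plate runs with the error structure
  the analysis must survive: Eq. above for *D*(c), position- and
  time-dependent evaporation with concentration-dependent suppression,
  ACF noise over averaged acquisitions, second particle populations
  (~43 nm soluble aggregates at ~12% intensity), gross per-well
  outliers; fully reproducible from (layout, parameters, seed).
* **ACF analysis** — second-order cumulant fits (Γ, PDI, baseline, SOS
  quality gates) and non-negative Tikhonov-regularised size
  distributions with peak extraction.
* **k_D pipeline** — per-concentration Grubbs outlier screening
  (two-sided extreme studentized deviate, iterated), OLS fit of
  *D* vs *c* with *k*<sub>D</sub> = slope/intercept, infinite-dilution
  radius extrapolation.
* **Variability statistics** — pooled intra-plate CVs, one-way and
  repeated-measures ANOVA with the *F* > *F*crit and *p* ≤ 0.05 rule,
  Bonferroni-corrected post-hoc t-tests, span metrics, and
  approach-comparison summary tables.
* **Design tools** — two recommended API-efficient screening layouts
  with exact material budgets, encodings of the published experimental
  layouts and well-grouping approaches, and Monte-Carlo scoring of
  candidate designs.

## Worked example

Simulate a small screen (one formulation, 4 concentrations × 5
replicates in centre wells) with the default instrument noise and
evaporation, analyse it, and estimate *k*<sub>D</sub> with outlier
screening:

```r
library(platekd)

cc <- c(2, 5, 10, 14)   # mg/mL
wells <- do.call(rbind, lapply(seq_along(cc), function(j) {
  data.frame(well = format_well_address(1:5, 1 + j), role = "sample",
             formulation_id = "lys", concentration_mg_ml = cc[j],
             replicate = 1:5, fill_volume_ul = 30)
}))
lay <- plate_layout(wells, plate_id = "demo")

truth <- list(lys = formulation_truth("lys", kD = 57, D0 = 1.30e-10))
run <- simulate_plate(lay, truth, seed = 42)
res <- analyze_plate(run)
head(res[, c("well", "D_m2_per_s", "R_H_nm", "PDI", "SOS")], 3)
#>   well   D_m2_per_s   R_H_nm         PDI       SOS
#> 1   B3 1.448991e-10 1.698751 0.007510668 22.483368
#> 2   B4 1.640757e-10 1.500207 0.000000000 13.766931
#> 3   B5 2.050569e-10 1.200386 0.005426521  6.001832

estimate_kd(res, lay)
#>   fit_id formulation_id           D0 kD_mL_g        R2 n_points_used n_excluded
#> 1    lys            lys 1.300169e-10 56.7168 0.9969178            20          0
```

The per-well diffusion coefficients rise with concentration (positive
*k*<sub>D</sub>); the fit recovers the simulated truth of 57 mL/g to
well under a percent, with *D*₀ ≈ 1.30×10⁻¹⁰ m²/s (a ~1.9 nm
hydrodynamic radius). With an aggressive evaporation setting or edge
wells in the layout the same pipeline shows the characteristic
*k*<sub>D</sub> depression and inflated CVs; `monte_carlo_design_eval()`
quantifies exactly that per design.

Generate and cost a recommended screening plate:

```r
lay <- recommended_design("low_risk")   # 8 formulations, 240 wells
api_budget(lay)$total_mg
#> [1] 43.2
attr(acquisition_schedule(lay), "duration_s") / 3600
#> [1] 5
validate_layout(lay)                    # zero findings
```

A thin command-line wrapper covers the same flows:

```sh
exec/platekd design --kind low_risk --out plate_map.csv
exec/platekd simulate --layout plate_map.csv --kd 57 --seed 1 --out sim/
exec/platekd analyze --measurements sim/run1_measurements.csv \
    --layout plate_map.csv --out analysis/
```

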