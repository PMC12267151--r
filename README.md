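# tracerkin

Stable-isotope tracer kinetics for oral-bolus studies in growing animals.

`tracerkin` is for metabolism researchers who run oral ¹³C-tracer tests —
for example U-¹³C₅ glutamine or U-¹³C₆ glucose boluses in suckling piglets —
and need a tested, reproducible path from raw instrument readouts to
whole-body kinetic endpoints. It covers:

* **Enrichment calibration** — GC-MS isotopologue peak-area ratios → molar
  percent excess (MPE) through an OLS calibration line; IRMS δ¹³C → atom
  percent excess (APE) by standard isotope-ratio arithmetic; baseline
  correction against the pre-bolus sample.
* **Peak-curve fitting** — Bateman (one-compartment absorption–elimination),
  log-normal-peak and gamma-variate families fitted by bounded
  Levenberg–Marquardt least squares, winner selected by AICc; analytic
  E\_max, T\_max and windowed AUC.
* **Kinetic endpoints** — rate of appearance `Ra = D / (AUC/100)` with D the
  tracer dose in mmol/kg and AUC in MPE·h; ¹³C recovery in CO₂
  (`n(¹³C) = AUC/100 × r(CO₂)`, normalized by the RBC-to-breath factor) as a
  whole-body oxidation proxy; gluconeogenic conversion
  `100 × AUC(¹³C₃-Glc)/AUC(¹³C₅-Gln)`.
* **Gut-function probes** — lactulose/mannitol and xylose tests with
  limit-of-quantification censoring (LOQ/2 substitution, flags preserved)
  and the same E\_max/T\_max/AUC machinery.
* **Design statistics** — noncentral-F power and sample size for 2×2
  factorials with Cohen's f, 1.5×IQR outlier flagging within cells, BMI and
  ponderal index.
* **A synthetic cohort generator** — the full 2×2 factorial study layout
  (12/12/11/11 animals from 18 litters, litter random effects, the ten-point
  sampling schedule, 5% multiplicative noise) with a per-animal ground-truth
  table, so the whole pipeline is testable end to end without any data
  download.

## Worked example

Calibrate, fit one animal's plasma glutamine-tracer curve, and compute its
rate of appearance:

```r
library(tracerkin)

cal <- build_calibration(known_mpe = c(0, 0.5, 1, 1.5, 2, 2.5),
                         measured_ratio = c(0.004, 0.256, 0.507, 0.762, 1.013, 1.262))
cal
#> <calibration_model> MPE = 1.98501 * ratio + -0.00849618  (n = 6, residual SD 0.0031 MPE, valid 0-2.5 MPE)

raw <- enrichment_curve(
  time_min = c(-15, 30, 60, 90, 120, 150, 180, 210, 240, 300),
  value    = c(0.021, 1.151, 0.962, 0.773, 0.615, 0.497, 0.402, 0.326, 0.267, 0.179),
  animal_id = "P001", analyte = "Gln-m5", unit = "MPE")
fit <- fit_peak_model(baseline_correct(raw))
fit
#> <peak_fit> family = bateman
#>   Emax = 1.138, Tmax = 25.52 min, AUC[0,300] = 162.9 (trapezoid 153.2)
#>   params: A = 1.4763, ka = 0.11411, ke = 0.007516, t0 = 0
#>   AICc = -89.909, RMSE = 0.002491, n = 9

D <- dose_to_mmol(gln_tracer_dose())   # 10 mg/kg of the 151.16 g/mol labelled species
rate_of_appearance(D, fit$auc, auc_unit = "MPE_min")
#> [1] 2.441769
```

The fitted curve peaks at 1.14 MPE about 26 min after the bolus; its
0–300 min AUC of 163 MPE·min (2.71 MPE·h) together with the 0.0662 mmol/kg
tracer dose gives a glutamine rate of appearance of 2.4 mmol/(kg·h) — the
physiologic magnitude for a suckling piglet.

A complete synthetic study, analyzed end to end:

```r
co  <- simulate_cohort(sim_config(), seed = 42)   # 46 animals, 8 analytes
res <- analyze_cohort(co$curves)
subset(group_summary(res$kinetics, co$animals), variable %in% c("ra_gln", "ra_glc"))
#>      group variable mean   sem  n
#> 1  LBW-Gln   ra_gln 3.19 0.371 12
#> 2  LBW-Gln   ra_glc 6.35 0.654 12
#> 11   LBW-W   ra_gln 3.12 0.204 11
#> 12   LBW-W   ra_glc 5.37 0.422 11
#> 21 NBW-Gln   ra_gln 3.36 0.356 12
#> 22 NBW-Gln   ra_glc 5.19 0.571 12
#> 31   NBW-W   ra_gln 2.82 0.246 11
#> 32   NBW-W   ra_glc 7.46 0.622 11
```

Glucose appears faster than glutamine in every cell, as expected when the
gut consumes glutamine first-pass. `run_pipeline("out/", seed = 42)` writes
all stage tables plus a `manifest.json` with per-file checksums; identical
seed and configuration reproduce identical checksums.

## Documentation

The methods vignette (`vignettes/tracer-kinetics-methods.Rmd`) documents
the models and their assumptions, the unit conventions (the MPE/100
percent-scale convention that Ra hinges on), the recovery-mode choice, the
lag-identifiability rule in the curve fitter, what the synthetic cohort
does and does not emulate, and known limitations.
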