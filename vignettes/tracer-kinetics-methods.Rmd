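---
title: "Methods: oral-bolus tracer kinetics, from instrument readout to whole-body endpoints"
author: "tracerkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oral-bolus tracer kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracerkin)
```

## The problem

In an oral-bolus stable-isotope tracer study, an animal receives a single
dose of a uniformly labelled substrate — here U-¹³C₅ glutamine (10 mg/kg,
99.5 atom%, with a 0.33 g/kg unlabelled carrier) or U-¹³C₆ glucose
(10 mg/kg, 99 atom%, carrier 0.4 g/kg) — and blood is sampled at −15
(basal) and 30, 60, 90, 120, 150, 180, 210, 240 and 300 min. Three kinds
of readout arise:

* **GC-MS isotopologue peak-area ratios** (e.g. m+4/m+0 for the
  glutamine fragment, m+6/m+0 and m+3/m+0 for glucose), converted to
  molar percent excess (MPE) by a linear calibration against gravimetric
  standards spanning 0–2.5 MPE;
* **IRMS δ¹³C values** of CO₂ liberated from red blood cells, converted
  to atom percent excess (APE) by standard isotope-ratio arithmetic;
* **plasma sugar concentrations** (mmol/L) for the lactulose/mannitol
  and xylose gut-function probes.

From the resulting peak-shaped curves the pipeline derives the whole-body
endpoints: rate of appearance (Ra), ¹³C recovery in CO₂ (oxidation
proxy), the glutamine→glucose gluconeogenic conversion, and the
absorption-test summaries Emax/Tmax/AUC.

## Enrichment calibration

`build_calibration()` fits ordinary least squares *with intercept*,
mapping measured ratio → MPE. The intercept absorbs the
natural-abundance offset of the unspiked standard; forcing the line
through the origin would bias low enrichments. Predictions outside the
standard range are flagged `extrapolated` but kept (observed plasma peaks
of ~1.2 MPE sit comfortably inside 0–2.5 MPE); predictions below
−1 residual SD are clamped to zero with a flag. No isotopologue
correction-matrix deconvolution is applied: a single-ratio calibration is
adequate when the calibration standards are prepared from the same
tracer.

For CO₂, `delta_to_ape()` uses the VPDB reference ratio
R\_std = 0.0111802 (overridable); with R(δ) = R\_std(δ/1000 + 1) and atom
fraction AF = R/(1+R),

APE = 100 × (AF(δ\_sample) − AF(δ\_basal)).

`baseline_correct()` subtracts the −15 min basal value so every curve
starts at exactly zero; negative corrected values are *retained* for
fitting (they are unbiased noise; truncating them would bias AUCs
upward) and only flagged.

## Peak-curve fitting

The central fitting stage (`fit_peak_model()`) mirrors the common
practice of summarizing bolus curves by a "best peak fit" from a small
library of right-skewed peak shapes:

* **Bateman** (one-compartment absorption–elimination):
  E(t) = A(e^(−ke(t−t0)) − e^(−ka(t−t0))), the mechanistic default for an
  oral bolus; Tmax = t0 + ln(ka/ke)/(ka−ke), closed-form windowed AUC.
* **Log-normal peak**: A·exp(−(ln t − ln Tm)²/2σ²), with closed-form AUC
  via the normal CDF.
* **Gamma variate**: A(t−t0)^α e^(−(t−t0)/β), closed-form AUC via the
  regularized incomplete gamma function.

Each family is fitted by bounded Levenberg–Marquardt least squares on
log-transformed parameters (positivity and ka > ke by construction), with
up to five deterministic moment-based starts, tolerance 1e−10 on the sum
of squares and 500 iterations per start. The winner is the lowest AICc;
ties within 1e−9 go to the family with fewer parameters, then to the
registry order (Bateman < log-normal < gamma).

Two numerical choices matter:

* **Lag identifiability.** When the curve's maximum sits at the *first*
  post-bolus sample, the rise phase is unobserved and the lag t0 of the
  lagged families is unidentifiable; fitting it anyway lets t0 wander
  into the unsampled 0–30 min region and systematically clips the AUC.
  The default `lag = "auto"` therefore frees t0 only when a rise is
  actually sampled (as it is for the delayed CO₂ curves, Tmax ≈ 60–145
  min) and pins t0 = 0 otherwise. This removes a several-percent
  downward AUC bias for early-peaking plasma curves (Tmax ≈ 30 min).
* **Rate-ratio bound.** ka/ke is capped at 50: beyond that the Bateman
  curve is an indistinguishable step-rise on this schedule, and
  absorption half-lives under ~2 min are not physiologic for an oral
  bolus delivered to a suckling gut.

The AUC integration window is fixed to the sampling period, [0, 300]
min; the unobserved tail is excluded deliberately (the recovery endpoint
is defined over the 5 h sampling period). Both the model-based AUC
(default) and the observed-grid trapezoid (with the implied (0, 0)
anchor) are reported; whether a published AUC was model-based or
trapezoidal is rarely stated, so both conventions are kept available via
`auc_method`. Degenerate inputs — fewer than five post-bolus points, no
positive value, or a flat series — fall back to the empirical summary
(maximum point, earliest time of the maximum, trapezoid AUC) with
`converged = FALSE`.

## From AUC to whole-body endpoints

With D the tracer dose in mmol/kg (`dose_to_mmol()`, using the molar
mass of the *labelled* species: 151.16 g/mol for ¹³C₅-glutamine, 186.18
for ¹³C₆-glucose — a ~3% difference from the unlabelled masses),

Ra [mmol/(kg·h)] = D / (AUC/100),

where AUC is in MPE·h and the division by 100 converts percent-scale
enrichment to mole-fraction excess. This percent convention is the only
one that lands Ra in the physiologic 2–6 mmol/(kg·h) range given doses
of ~0.066 mmol/kg and AUCs of 2–3 MPE·h; omitting it produces answers
off by two orders of magnitude, which is why all tables carry explicit
MPE/APE unit tags.

¹³C recovery converts the CO₂ APE·h AUC into mmol of excess ¹³C using
the CO₂ production rate r(CO₂) = 48 mmol/(kg·h) (a doubly-labelled-water
constant for suckling piglets, configurable), divides by the excess ¹³C
administered (`tracer_excess_13c()`: D × n\_labelled × (purity −
natural abundance); the carrier is at natural abundance and contributes
zero excess), and divides by the RBC-to-breath correlation factor (0.90
for the glutamine tracer, 0.98 for glucose). Two modes are implemented:
the **dimensional** default, n(¹³C) = AUC/100 × r(CO₂); and a
**literal** mode that additionally multiplies by the sampling
period t = 5 h, reproducing the equation form in which such recoveries
are sometimes printed. The literal form carries units mmol·h/kg and
equals exactly 5× the dimensional value; neither mode is asserted to
reproduce any particular published recovery table, because the basis of
r(CO₂) (per kg body weight vs per metabolic weight) cannot be pinned
down from a dimensional argument alone. The mode used is recorded in
every output.

Gluconeogenic conversion is the unit-free quotient
100 × AUC(¹³C₃-glucose)/AUC(¹³C₅-glutamine) from curves measured in the
same test.

## Gut-function probes

Sugar concentration curves share the identical fitting path — one source
of Emax/Tmax/AUC truth for tracers and sugars. Values below the assay
LOQ (lactulose 0.03, mannitol 0.06, xylose 0.01 mmol/L) are substituted
by LOQ/2 with the censoring flag preserved; this simple substitution is
appropriate for the sparse censoring seen here, and the flag lets users
drop censored points instead. A fully censored series (the typical
lactulose outcome when barrier function is intact) is reported as not
quantifiable, and the lactulose:mannitol ratio is only computed when
both AUCs are quantifiable. Note the substitution is downward for values
in [LOQ/2, LOQ) but necessarily upward for values below LOQ/2; summary
monotonicity holds for the censored band, not pointwise below LOQ/2.

## Design statistics

`required_sample_size_2x2()` computes noncentral-F power for each main
effect of a balanced 2×2 between-subjects design with numerator df 1,
denominator df N − 4 (cells model with interaction) and noncentrality
λ = f²N, and returns the smallest per-cell n at which both effects reach
the target. With f = 0.5 and 0.45, α = 0.05 and power 0.80 this gives
n = 11 per group (power 0.830 at n = 11 vs 0.791 at n = 10 for the
weaker effect). The denominator-df convention is a documented choice;
power tools differ here, and this is the convention under which the
study-sized answer is reproduced.

Outlier screening uses Tukey fences (Q1 − 1.5·IQR, Q3 + 1.5·IQR) with
type-7 (linear-interpolation) quartiles, computed within factorial
cells. The function only *flags*; removal is left to the analyst, since
a flagged value should only be dropped when it demonstrably breaks
distributional assumptions. Zootechnical indices are BMI = BW/CRL² and
PI = BW/CRL³. Mixed-model group comparisons (random litter effects,
repeated-measures covariance structures, post-hoc tests) are out of
scope by design: the pipeline emits tidy per-animal tables for the
analyst's preferred mixed-model tool.

## The synthetic cohort

`simulate_cohort()` generates the full study layout: four cells
(LBW-Gln 12, NBW-Gln 12, LBW-W 11, NBW-W 11) built as low/normal
birthweight littermate pairs drawn from 18 litters, birthweights in the
defining windows (0.8–1.2 and 1.4–1.8 kg), linear bodyweight
trajectories with per-group ADG, and per-animal curves on the ten-point
schedule.

Ground truth is parameterized the way the endpoints are defined: each
animal's plasma tracer curve is a Bateman shape whose windowed AUC is
*derived from its drawn true Ra* through AUC = D/Ra × 100, with the
drawn Tmax fixing the rates at a constant shape ratio ka/ke = 10. The
value 10 was chosen because it reproduces the joint relations of the
published plasma-glutamine group summaries (an Emax 1.18/Tmax 31.3 curve
implies AUC ≈ 169 vs the printed 164 MPE·min); no two-shape-parameter
family can match all three of Emax, Tmax and AUC exactly, and AUC + Tmax
are prioritized because they drive the kinetic endpoints. The
¹³C₃-glucose curve is the glutamine curve's AUC scaled by the drawn
conversion; CO₂ curves are delayed Batemans (lag 15 min) matched to the
drawn CO₂ AUC and Tmax, with true recovery *derived* from that AUC in
dimensional mode; sugar curves are matched to (Emax, Tmax), with
lactulose's default peak (0.012 mmol/L) deliberately below its LOQ.
Default cell means are the published group means wherever one exists
(Ra, Tmax, conversion, CO₂ AUC, xylose peak); mannitol and lactulose
targets are plausible values chosen once.

Biological variability is a shared per-litter log-normal intercept
(SD 0.15) plus independent per-animal log-normal deviations (SD 0.25)
applied to every kinetic parameter — magnitudes read off the published
least-squares SEMs (≈0.25 at n ≈ 11 for a mean Ra of 2.68 implies a
total CV near 0.3). Draws are mean-centred on the log scale, so the
configured cell means are the *expected* truth means. Measurement noise
is multiplicative log-normal with CV 5% and the mean-preserving
parameterization x·exp(z − s²/2); the basal sample gets an absolute
noise floor (SD 0.005 enrichment units). Draw order is fixed, so a seed
fully determines the dataset, byte for byte.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: tracer dilution by ongoing milk intake
(curves here derive from clean single-compartment shapes), non-Bateman
curve shapes (enterohepatic or biphasic absorption), assay drift or
autocorrelated residuals, missing samples and catheter failures, and
litter-by-treatment interactions. Recovery of the configured truth
demonstrates the estimation pipeline's correctness, not the biological
model's.

## Problem sizes and validation choices

The package validates itself at three scales, chosen as the smallest
sizes that make each claim statistically meaningful: single curves
(noiseless recovery to machine precision; closed forms vs adaptive
quadrature at 1e−8), the study-sized 46-animal cohort (end-to-end smoke
and determinism checks), and a 1000-animal cohort at 5% noise on which
the fit→AUC→Ra pipeline achieves a per-animal median absolute relative
error under 5% and per-cell group-mean Ra within 2% of the configured
truth. Monte-Carlo cross-checks (20,000-replicate ANOVA power; 1000
calibration replicates against the exact t-distribution coverage) pin
the analytic formulas to simulation.

## Known limitations

* Ra from a single oral bolus conflates absorption and first-pass
  extraction with systemic appearance; it is the standard bolus-AUC
  estimate, not a two-pool flux.
* The published recovery equation's time factor makes its units
  ambiguous; both conventions are provided and flagged, and recovery
  values should be compared only within one convention.
* AUC extrapolation below the first sample (0–30 min) is model-driven;
  with Tmax near 30 min different families legitimately disagree by a
  few percent there, which bounds the accuracy of any single-curve AUC.
* The lag rule is data-driven: a curve whose true peak precedes the
  first sample is summarized with t0 = 0 by construction.
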