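---
title: "Methods: vis-NIR calibration of sugarcane quality with canespec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vis-NIR calibration of sugarcane quality with canespec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canespec)
```

## The problem

Mills determine cane quality — Brix, Pol, Fibre, Pol of cane and TRS — by
slow wet-lab assays. Vis-NIR spectroscopy can replace them if a multivariate
calibration maps absorbance spectra to the laboratory values. `canespec`
implements such a calibration pipeline end-to-end for four
sample-preparation types (skin scan of billets SS, cross-sectional scan
CSS, defibrated cane DF, raw juice RJ), together with a synthetic-data
generator that stands in for mill spectra, which are rarely public.

This vignette documents the model, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic experiments do
and do not demonstrate.

## The synthetic campaign

`generator_config()` describes a campaign; its defaults are the conditions
the pipeline is designed for:

* **302 samples**, measured as all four types with **9 replicate scans**
  each.
* A two-detector grid: 373–1011 nm (CCD) and 1170–2222 nm (InGaAs), both at
  5 nm. The inter-detector gap is preserved; nothing is ever interpolated
  across it.
* Quality parameters drawn from a multivariate Gaussian with means, SDs and
  ranges typical of a harvest season (e.g. TRS 137.66 ± 14.48 kg Mg⁻¹,
  range ≈ 87–174) and the correlation structure of mill reference data: the
  four sugar-related parameters mutually correlated at 0.94–0.99, Fibre
  essentially uncorrelated (r = 0.05). Draws are clipped to the configured
  ranges; the clipped fraction is recorded and stays below 1% in
  expectation (the ranges sit at roughly ±3 SD). A non-PSD correlation
  matrix is rejected outright — no silent nearest-PSD repair.
* Spectra follow a Beer–Lambert surrogate: each parameter contributes
  Gaussian absorption bands placed in the overtone regions known to carry
  sugar and fibre information (≈960, 1139, 1360, 1600, 1850–1900,
  2100 nm), so variable-importance analyses have a known ground truth.
  On top of the analyte signal sit (i) a **dominant matrix background** —
  broad water/cellulose bands of order 1 absorbance with 2% between-sample
  amplitude variation; (ii) per-type interference bands (a wax-like band at
  1730 nm for SS, water-dominated bands for CSS/RJ, a 1930 nm band for DF)
  with 30% between-sample amplitude variation unrelated to quality; and
  (iii) per-scan multiplicative scatter (SD 0.02), additive baseline
  (SD 0.01) and white noise (SD 0.002 absorbance, scaled per type).
  Replicate scans share the sample signal and differ only in scatter,
  baseline and noise.

The matrix background deserves a note: real cane spectra are dominated by
water and cellulose absorption, and SNV (below) normalises each spectrum by
its own standard deviation. Without a dominant background that SD is
proportional to the analyte signal itself and SNV would destroy exactly the
information the calibration needs — a failure mode no real spectrum
exhibits. The background makes the surrogate behave like real data under
the standard preprocessing.

What the generator does **not** emulate: radiative transfer or particle
scattering physics, non-linear detector response, wavelength drift,
temperature effects, variety differences, or reference-method bias.
Passing recovery tests on this generator therefore shows the pipeline is
correct and well-conditioned, not that any particular mill will reach the
same accuracy.

## Preprocessing

The fixed order is SNV → Savitzky–Golay second derivative → Pareto scaling.

* **SNV** centers each spectrum on its mean and scales by its sample SD
  (n−1 denominator everywhere in this package). It removes additive
  baseline and multiplicative scatter per scan and is invariant to positive
  affine transforms.
* **Savitzky–Golay**: window 11 points, polynomial order 2, second
  derivative. Each detector segment is filtered independently; the filter
  never spans the gap (the gap is ~160 nm, thirty times the step). The
  w−1 edge points of each segment are produced by the filter's one-sided
  polynomial fits rather than dropped, so the grid length is preserved. The
  output is the raw per-index derivative, not divided by the squared
  wavelength step: PLS after Pareto scaling is invariant to that constant,
  so only the convention needs fixing.
* **Pareto scaling** centers each wavelength and divides by the square root
  of its SD. It is fitted on calibration rows only and refit inside every
  cross-validation training fold, so held-out folds never leak into the
  column statistics (a flag allows the global-fit variant for comparison
  with software that scales once).

Before preprocessing, wavelengths below 699 nm are discarded (pigment
absorption and detector noise dominate the visible range in field scans of
cane) and the trailing run of bands whose CV across samples exceeds 5× the
median CV is dropped — the long-wavelength detector tail is the usual
offender. The threshold multiple is configurable because no universal
cut-off exists; both trims are logged in the result's provenance. The
retained band count is grid-dependent and deliberately never hard-coded.

## Sample selection and calibration

The four types' preprocessed spectra are concatenated feature-wise (fixed
order SS, CSS, DF, RJ) and split once by the classic Kennard–Stone max–min
rule at 75/25, so every type shares the same calibration (n = 227 of 302)
and validation (n = 75) samples and the pairwise model comparisons are
paired. Distances are Euclidean on the concatenated SNV+SG spectra (raw vs
preprocessed distances is a genuine free choice; preprocessed matches what
the model sees, and is switchable by calling `kennard_stone()` directly).

PLS models are fitted by NIPALS (PLS1). Venetian-blinds cross-validation
assigns calibration sample *i* (in Kennard–Stone selection order, which is
therefore pinned) to fold *i* mod 10. The component count is chosen as the
smallest *k* whose squared held-out residuals do not differ significantly
(sign-flip randomization test, α = 0.05) from those at the RMSECV minimum —
the parsimony rule common in chemometrics practice, made explicit and
distribution-free here. When a cross-validation training fold runs out of
rank (possible on near-noiseless synthetic data), the fit keeps the
components it could extract and the error curve flattens instead of
erroring.

## Outlier handling

Calibration-only, at most three passes, each pass refitting the model:

1. **Spectral outliers**: a sample is removed only when *both* its
   Hotelling T² (leverage in score space, F-distribution limit
   `h(n−1)/(n−h) F(1−α; h, n−h)`) and its Q residual (squared distance to
   the model plane, Jackson–Mudholkar limit from the residual eigenvalues;
   a χ² moment-matching alternative is available) exceed their 5%
   thresholds. The both-rule reads the influence plot literally: points
   extreme in only one direction are retained. An either-rule flag exists.
2. **Reference outliers**: |calibration residual| > 3 × RMSEC.

Validation samples are treated as unknowns: their T²/Q statistics can be
computed and reported but they are never removed by default. A guard rail
warns when more than 10% of the calibration set is discarded. The screening
fits use a provisional component count (default 10) because the loop runs
before cross-validation; the final model is refit after cleaning with the
CV-selected count.

## Metrics and comparisons

`RMSE = sqrt(mean((y − ŷ)²))`. R² is the squared Pearson correlation of
reference and predicted values by default; the `1 − SSE/SST` convention is
available (`r2_method = "ss"`) because the two differ off the 45° line and
published tables rarely say which was used. RPIQ divides the interquartile
range of the *evaluation set's reference values* by the RMSE; quartiles use
linear interpolation between order statistics (R's default type 7). At zero
RMSE the RPIQ is reported as undefined rather than infinite.

The randomization test compares two models on the shared validation set
through `d_i = e1_i² − e2_i²`: under equal accuracy the signs of the paired
differences are exchangeable, so the null is built by independent sign
flips — exhaustively (2ⁿ patterns) for n ≤ 15, else 19,999 Monte-Carlo
draws — with the add-one two-sided p-value `(#{|t*| ≥ |t|} + 1)/(N + 1)`.
Squared differences are the canonical statistic for this test; absolute
differences are available behind a flag. No multiplicity correction is
applied across the 6 pairs × 5 attributes table, matching common practice
for this diagnostic.

VIP is computed from the loading weights and the per-component explained
response variance; `mean(VIP²) = 1` is an algebraic identity used as a
self-check, and wavelengths are categorised at the conventional 1.0 / 0.8
thresholds. For a single-component model VIP reduces to
`√p · |w_j| / ‖w‖`.

## Numerical conventions and degenerate inputs

* Sample SD (n−1) everywhere; wavelength comparisons at 1e-6 nm.
* A constant spectrum makes SNV error explicitly (naming the sample); a
  zero-variance wavelength is centered, left unscaled and flagged.
* Zero-mean bands have undefined CV and are treated as exceeding the trim
  threshold.
* NIPALS stops with an error when asked for more components than the
  effective rank (`allow_fewer = TRUE` relaxes this inside resampling).
* Kennard–Stone ties (duplicate rows) are allowed and broken
  deterministically by index order.
* All randomness flows through explicit seeds; per-stage seeds are derived
  arithmetically from the master seed so results are independent of call
  order. Identical configs give byte-identical CSV artifacts.

## Problem sizes used in the test suite

Unit tests run reduced synthetic studies (24–80 samples, 1–3 replicates);
the study-level checks run the full campaign (302 samples × 4 types × 9
replicates — about 11,000 scans), which completes in well under a minute,
plus a 1000-repetition null-calibration of the randomization test at the
study's validation size (n = 75). These sizes were chosen to exercise the
full pipeline at its design scale while keeping the suite quick to run.

The study-level expectations are: the 75/25 split of 302 samples yields
227/75; RPIQ values recomputed from published validation quartiles and
errors of a mill-scale benchmark reproduce the published figures at two
decimals; VIP normalisation holds for every fitted model; the
randomization test holds its nominal 5% size within Monte-Carlo bounds
[0.03, 0.07]; Kennard–Stone, the SG filter, full-rank PLS and T² match
independent oracles; the full pipeline reaches median external R²p ≥ 0.9
for the sugar parameters with top-VIP wavelengths inside the generating
bands; and the outlier loop removes three planted gross outliers (two
spectral, one reference) with at most one false positive.

## Known limitations

* The generator's linear band model cannot probe non-linear
  spectra–composition relationships; conclusions about SVM/ANN-type models
  are out of scope.
* Pol of cane and TRS are generated directly with the configured
  correlation structure; the empirical payment formulas that derive them
  from Brix/Pol/Fibre are not implemented.
* The x-side energy decomposition `‖x‖² = ‖fitted‖² + Q` holds in
  aggregate (residuals are orthogonal to scores) but not row-by-row,
  because the PLS x-decomposition is oblique; Q statistics are exact, only
  the per-row identity is unavailable as a check.
* No MSC, detrending, OSC or wavelet preprocessing; no reflectance ↔
  absorbance conversion; no resampling across instruments.
* No figure rendering: PCA overviews, VIP profiles and influence statistics
  are returned as tables for the user's plotting tool of choice.
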