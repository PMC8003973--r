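# canespec

Chemometric calibration of sugarcane quality parameters from visible/near-
infrared (vis-NIR) spectra.

Sugar mills price cane on a handful of laboratory parameters — Brix (soluble
solids, %), Pol (apparent sucrose, %), Fibre (%), Pol of cane (%) and TRS
(total recoverable sugars, kg Mg⁻¹). `canespec` implements a complete,
reproducible pipeline for replacing those wet-lab assays with PLS
calibrations of vis-NIR spectra measured on four sample-preparation types:
skin scanning of billets (SS), cross-sectional scanning of billets (CSS),
defibrated cane (DF) and raw juice (RJ). A synthetic-data module emulates a
full mill campaign (302 samples, two detector segments at ~5 nm with a gap,
nine replicate scans per sample type, realistic parameter correlations), so
every stage of the pipeline is testable without instrument data.

## What it computes

For spectra `X` (samples × wavelengths, absorbance) and a quality parameter
`y`, the pipeline is:

1. **Replicate averaging** — each sample's nine successive scans are averaged.
2. **Wavelength trimming** — the noisy visible region (< 699 nm) is removed,
   and the unstable high-CV tail of the long-wavelength detector is dropped
   (per-band CV > k × median CV, suffix only).
3. **Preprocessing** — standard normal variate (SNV) per spectrum, then a
   Savitzky–Golay second derivative (window 11, polynomial order 2) applied
   per detector segment, then Pareto scaling (column centering and division
   by √SD) fitted on calibration rows only.
4. **Sample selection** — one Kennard–Stone max–min split (75% calibration /
   25% validation) of the four sample types concatenated feature-wise, so
   all types share the same calibration and validation samples.
5. **Calibration** — NIPALS PLS1 with venetian-blinds cross-validation (10
   interleaved splits). The component count is the smallest number of latent
   variables whose RMSECV is not significantly higher than the curve minimum
   (paired sign-flip randomization test on squared CV residuals, α = 0.05).
6. **Outlier handling** — up to three passes of {fit → remove samples
   extreme in *both* Hotelling T² and Q residual at the 5% level → remove
   samples with |residual| > 3 × RMSEC → refit}, on calibration rows only.
7. **Reporting** — RMSEC / RMSECV / RMSEP with
   `RMSE = sqrt(mean((y - ŷ)²))`, R²c / R²p (squared Pearson correlation),
   `RPIQ = (p75 − p25) / RMSEP` from the validation reference quartiles, and
   the variable importance in projection per wavelength,

   `VIP_j = sqrt( p · Σ_k Z_k (w_jk / ‖w_k‖)² / Σ_k Z_k )`,

   where `w_k` are loading weights and `Z_k` the per-component explained
   fraction of response variance (VIP > 1 influential, 0.8–1 moderate).
8. **Model comparison** — a distribution-free randomization test of equal
   prediction accuracy for every pair of sample types (sign-flipped mean
   difference of squared validation errors, exhaustive for n ≤ 15).

## Worked example

```r
library(canespec)

cfg <- study_config(
  generator = generator_config(n_samples = 120, n_replicates = 3, seed = 7),
  seed = 7)
res <- run_study(cfg)
res
```

```
<study_result> 120 samples (90 cal / 30 val), 19 models
   attribute sample_type  n_lv rmsec rmsecv rmsep   r2c   r2p  rpiq
 1 Brix      SS              1 0.503  0.524 0.516 0.912 0.820  3.58
 2 Pol       SS              1 0.518  0.536 0.452 0.919 0.879  3.50
 3 Fibre     SS              3 0.401  0.537 0.504 0.950 0.844  3.01
...
19 TRS       RJ              1 3.50   3.58  3.49  0.933 0.858  2.40
```

One row per sample type × attribute (Fibre is never modelled from raw
juice): the selected number of latent variables, the calibration /
cross-validation / external-prediction errors in the attribute's units, the
calibration and prediction R², and the RPIQ (values ≳ 2.5 indicate a model
usable for screening). Pairwise accuracy comparisons are in `res$pvalues`:

```r
subset(res$pvalues, attribute == "TRS")
```

```
  attribute pair       type1 type2 statistic p_value
1 TRS       SS vs. CSS SS    CSS     -1.07     0.743
2 TRS       SS vs. DF  SS    DF      -0.779    0.782
...
6 TRS       DF vs. RJ  DF    RJ      -0.0203   0.996
```

A p-value below 0.05 means the two sample types predict that attribute with
significantly different accuracy on the shared validation set. VIP profiles
per wavelength are in `res$vip`; `write_study_result(res, "out/")` writes
all tables as CSV plus a provenance JSON. A study is fully described by a
YAML config (see `inst/extdata/example_study.yaml` and
`read_study_config()`).

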