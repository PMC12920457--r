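# tanninspec

Near-infrared (NIR) calibration of tannin content in walnut kernels,
packaged as a tested, reusable chemometrics pipeline in R.

Tannins are the polyphenols responsible for walnut astringency; their
reference quantification (a colorimetric assay against a gallic-acid
standard curve, reported in mg/g) is slow and reagent-hungry.  NIR
reflectance over 4000–10000 cm⁻¹ carries tannin information through O–H
overtone and combination bands (near 7000 cm⁻¹ and in 4000–5000 cm⁻¹),
and a calibration model can replace the assay for routine screening.
`tanninspec` implements the full modelling workflow and a synthetic
spectra generator that emulates the statistical structure of such a
study, so every stage is testable without instrument data.

## The workflow

Given scan-level reflectance `v_ij` (sample *i*, band *j*) and reference
tannin `y_i`:

1. **Replicate averaging** — three scans per sample are averaged to one
   spectrum per sample.
2. **Monte-Carlo outlier screen** — repeated random 60/40 splits; each
   iteration fits a mean-centred NIPALS PLS regression (20 latent
   variables) and accumulates each sample's absolute validation errors.
   Samples whose error mean or SD exceed the configured cutoffs are
   removed.
3. **Transform bank** — 12 spectral forms: R, 1/R, lgR, lg(1/R) and
   their first/second divided-difference derivatives along the
   wavenumber axis (note lg(1/R) = −lgR exactly, so mirrored pairs share
   their absolute-correlation structure).
4. **Continuous wavelet transform** — for selected forms,
   `w(a,b) = Σ_j v_j (1/√a) ψ((j−b)/a)` with a unit-norm gaus4 mother
   wavelet (fourth derivative of a Gaussian) at dyadic scales 2¹…2¹⁰,
   symmetric-reflection boundary handling, same-length output.
5. **Characteristic-band selection** — per-feature Pearson correlation
   with tannin; features with `p < 0.01` and `|r|` above the critical
   value (from inverting `t = r√((n−2)/(1−r²))`) are retained; per
   source the wavelet scale maximising mean |r| is chosen.
6. **Random-forest calibration** — a shared 6:4 split; 200 trees,
   minimum leaf size 10, optional seeded random search (CV-RMSE
   objective) over the per-split feature fraction; evaluated by
   `R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)²`, `RMSE`, and `RPD = SD(y)/RMSE`
   (RPD > 2 conventionally indicates a robust calibration).
7. **Shapley attribution** — interventional Shapley values of the best
   validation model (exact subset enumeration up to 12 features, seeded
   permutation sampling beyond), with ranking, beeswarm and waterfall
   exports.  `base + Σφ` equals each prediction exactly.

## Worked example

```r
library(tanninspec)

modes <- default_management_modes()
modes$baseline_offset <- 0        # only tannin-coupled bands informative

cfg <- pipeline_config(
  generator = generator_config(n_samples = 90, n_bands = 256,
                               management_modes = modes,
                               coupling_strength = 0.006,
                               scan_noise_sd = 0.005),
  mc = mc_config(n_iterations = 100),
  rf = rf_config(tuning_iterations = 0, n_trees = 100),
  scales = 2^(1:7),
  shap_n_permutations = 8, shap_n_explain = 15, shap_max_background = 30,
  seed = 42, verbose = FALSE)

report <- run_pipeline(cfg)
subset(report$comparison$table,
       input %in% c("R_CWT_128 full", "lg'R characteristic"))
```

```
                 input        set    R2  RMSE  RPD  r2_gap overfit
11 lg'R characteristic      train 0.877 0.896 2.88 0.31652    TRUE
12 lg'R characteristic validation 0.560 1.832 1.53 0.31652    TRUE
17      R_CWT_128 full      train 0.983 0.329 7.84 0.00721   FALSE
18      R_CWT_128 full validation 0.976 0.426 6.57 0.00721   FALSE
```

The wavelet-decomposed reflectance (`R_CWT_128`) calibrates tannin with
validation R² = 0.976, RMSE = 0.43 mg/g and RPD = 6.6 on this clean
synthetic set, while a raw first-derivative model overfits (train–val
R² gap 0.32, flagged in the `overfit` column).  `report$best_input`
names the winner; its Shapley ranking localises the influential
features:

```r
report$attribution_tables$ranking
#>     feature mean_abs_phi rank
#> 1  wn6352.9       0.0502    1
#> 2  wn6447.1       0.0470    2
#> ...
```

Each `mean_abs_phi` is the feature's average absolute contribution in
mg/g; with large-scale wavelet features each coefficient summarises a
broad spectral neighbourhood, so top features sit around — not exactly
on — the absorption centers.  `report_summary(report)` prints the
per-transform characteristic-band table, the per-scale mean |r| table,
the full 16-model comparison and the top-10 attribution in one go, and
`pipeline_config(output_dir = ...)` writes every stage table as CSV.

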