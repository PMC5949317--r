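# kmnir

Particle-size-aware Kubelka-Munk modelling of near-infrared (NIR) diffuse
reflectance spectra.

`kmnir` is for chemometricians and pharmaceutical analysts who build
quantitative NIR calibrations on powders — where the particle size of the
milled material changes the optics of every spectrum — and want the whole
chain from diffuse-reflectance physics to validated PLS models in one tested,
scriptable package.

## What it implements

The quantitative basis is Kubelka-Munk theory. For an optically thick powder
layer, the remission function ties the measured diffuse reflectance
R<sub>∞</sub> to the ratio of absorption (k) and scatter (s) coefficients:

$$f(R_\infty) = \frac{(1-R_\infty)^2}{2R_\infty} = \frac{k}{s},
\qquad A = -\log_{10} R_\infty,$$

with k proportional to analyte concentration and s inversely proportional to
particle diameter. On top of that core the package provides:

* **K-M analytics** — `remission_function()`, `invert_remission()` (the
  cancellation-free root), `absorbance_from_ratio()`,
  `ratio_from_absorbance()`, `estimate_scatter()`,
  `scatter_from_particle_size()`, and `linearity_profile()` /
  `linear_region_onset()`, which locate the near-linear region of A vs k/s
  used to justify linear calibration.
* **Preprocessing** — MSC, EMSC, SNV, nine-point Savitzky-Golay smoothing and
  derivatives, normalization and baseline subtraction, all fitted on
  calibration data only (`preprocess_fit()` / `preprocess_apply()`).
* **Chemometrics** — deterministic Kennard-Stone splitting
  (`kennard_stone_split()`), NIPALS PLS (`pls_fit()`, with `tidy()` /
  `glance()` / `predict()` / `autoplot()` methods), leave-one-out PRESS
  latent-variable selection (`loocv_press()`), and RMSEC/RMSECV/RMSEP,
  R², RPD reporting (`evaluate_model()`).
* **Synthetic data** — a physics-based generator (`simulate_dataset()`,
  `pure_scatter_dataset()`) emulating 30 base samples × 7 sieve fractions ×
  3 replicates over 780–2500 nm, with ground-truth k and s for closed-loop
  testing.
* **Study pipeline** — `run_full_study()` and friends: single-fraction model
  comparison, pooled ("mixed") 3-fraction models, cross-prediction of member
  fractions by a pooled model, and the K-M linear-region report, all written
  as plain TSV tables.

Everything takes and returns tibbles, so the pieces chain with the pipe.
The methods vignette (`vignettes/kubelka-munk-nir.Rmd`) documents the model,
the defaults, and every place a convention had to be chosen.

## Worked example

```r
library(kmnir)
library(dplyr)

remission_function(c(1, 0.5, 0.2))
#> [1] 0.00 0.25 1.60

absorbance_from_ratio(4)
#> [1] 0.9955904

# where does A vs k/s become linear (window R^2 >= 0.995, width 4)?
prof <- linearity_profile(0, 20, window_width = 4, step = 0.01)
linear_region_onset(prof, r2_threshold = 0.995)
#> [1] 4.6

# simulate the full 210-sample study and run the comparison
dat <- simulate_dataset(sim_config(seed = 1))
study <- run_full_study(dat$spectra, dat$references)

study$single$report |> filter(best) |>
  select(fraction_set, preprocess, n_latent, rmsep, r2_pred, rpd)
#> # A tibble: 7 × 6
#>   fraction_set preprocess n_latent  rmsep r2_pred   rpd
#> 1 355-850      RAW               3 0.0263   0.994 13.5
#> 2 250-355      SG9               7 0.0243   0.992 11.7
#> 3 180-250      SNV               2 0.0352   0.990 10.5
#> 4 150-180      SG9               4 0.0236   0.995 15.1
#> 5 125-150      MSC               2 0.0300   0.987  9.21
#> 6 90-125       MSC               2 0.0162   0.997 18.2
#> 7 <90          SG9               3 0.0290   0.991 10.9
```

Each row is the best preprocessing method for one sieve fraction: its PLS
model size (latent variables chosen by leave-one-out PRESS), the prediction
error on the Kennard-Stone validation set in mg·g⁻¹ (RMSEP), the validation
R², and RPD — the ratio of the validation references' spread to RMSEP, the
field's usual "is this calibration usable" number (≥ 3 is the conventional
bar). The cross-prediction comparison shows the pooled 90–180 μm model
matching or beating the single-fraction models for two of its three member
fractions:

```r
study$cross$comparison |>
  select(target_fraction, mixed_preprocess, mixed_rpd,
         single_preprocess, single_rpd)
#> # A tibble: 3 × 5
#>   target_fraction mixed_preprocess mixed_rpd single_preprocess single_rpd
#> 1 125-150         SG9                   10.7 MSC                     9.21
#> 2 150-180         EMSC                  16.1 SG9                    15.1
#> 3 90-125          MSC                   11.3 MSC                    18.2
```

`autoplot(study$single)`, `autoplot(prof)` and `plot_spectra(dat$spectra)`
give quick-look ggplots of the reports, the linearity profile and the raw
spectra.

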