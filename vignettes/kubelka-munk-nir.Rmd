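---
title: "Particle-size-aware Kubelka-Munk modelling of NIR diffuse reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-size-aware Kubelka-Munk modelling of NIR diffuse reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(kmnir)
library(dplyr)
```

## The problem

Near-infrared (NIR) diffuse reflectance spectroscopy is a fast, non-destructive
way to quantify an active constituent in a powdered material — here, an
iridoid-glycoside marker in a milled medicinal root, assayed in mg·g⁻¹ against
a chromatographic reference method. The catch is particle size. A powder's
diffuse reflectance depends not only on how much light it absorbs but on how
strongly it scatters, and scattering depends on the sieve fraction: coarser
powders scatter less, return less light, and show a higher apparent absorbance
at every wavelength, even when their chemistry is identical. Any calibration
model built on one sieve fraction therefore rests on different optics than a
model built on another, and pooling fractions mixes the two effects.

`kmnir` packages the whole analysis chain needed to study this quantitatively:
the Kubelka-Munk (K-M) optics, scatter-correction preprocessing, a
deterministic calibration/validation split, PLS regression with
cross-validated model-size selection, RPD-based model comparison across single
and pooled sieve fractions, and a physics-based spectra simulator so the
pipeline can be exercised and tested end to end without proprietary
instrument data.

## The Kubelka-Munk model

For an optically thick powder layer, the remission function links measured
diffuse reflectance $R_\infty \in (0, 1]$ to the ratio of the absorption
coefficient $k$ and scatter coefficient $s$:

$$f(R_\infty) = \frac{(1 - R_\infty)^2}{2 R_\infty} = \frac{k}{s},$$

and the apparent absorbance is $A = -\log_{10} R_\infty$, i.e.

$$A = -\log_{10}\!\left[1 + \frac{k}{s} - \sqrt{\left(\tfrac{k}{s}\right)^2 + 2\,\tfrac{k}{s}}\right].$$

Two qualitative facts drive everything downstream: $k$ grows linearly with
analyte concentration at fixed matrix, while $s$ is inversely proportional to
particle diameter. So concentration and particle size are entangled in $A$
through the single ratio $k/s$.

`remission_function()`, `invert_remission()`, `absorbance_from_ratio()` and
`ratio_from_absorbance()` implement this algebra elementwise over spectra.
A numerical note: the physical root of the remission quadratic is
$R_\infty = 1 + x - \sqrt{x^2 + 2x}$, which loses all precision to
cancellation at large $x$. The package always evaluates the algebraically
identical form $R_\infty = 1/(1 + x + \sqrt{x^2 + 2x})$, which is stable for
every $x \ge 0$ — there is no reason to reserve the stable form for large
ratios only, so no branch point exists.

## The linear region

$A$ is a concave function of $x = k/s$: steep near the origin, flattening
toward $A \approx \log_{10}(2x + 2)$ with curvature decaying like
$\log_{10}(e)/x^2$. Linear calibration therefore works best where the model
operates on the flat part of this curve. `linearity_profile()` makes that
operational: a window of fixed $k/s$ span slides over a configured range, a
straight line is fitted to $A$ vs $k/s$ on each window, and the window's
$R^2$ and maximum absolute residual are reported.

```{r linear-region}
prof <- linearity_profile(0, 20, window_width = 4, step = 0.01)
linear_region_onset(prof, r2_threshold = 0.995)
```

The defaults — range $[0, 20]$, window width 4, onset threshold
$R^2 \ge 0.995$ — are package choices: no standard criterion exists for
declaring a region of this curve "linear", so the package reports the full
profile and lets a configurable threshold define the onset. With these
defaults the onset lands just above $k/s = 4$, consistent with the
conventional observation that the curve is usable for linear modelling beyond
ratios of about four. Since absorbance is the measured quantity, this is
implemented with $A$ as the ordinate and $k/s$ as the abscissa.

Because windows far from the origin have tiny spreads in both coordinates,
the window fits center both variables globally before accumulating running
sums; otherwise $R^2$ near 1 would be swamped by floating-point cancellation
for ranges starting at large $k/s$.

One gap is deliberate: for a real powder, $k(\lambda)$ is unknown, and no
assumption-free way exists to split measured $A$ into $k$ and $s$.
`estimate_scatter()` therefore computes $s = k / f(R_\infty)$ only where $k$
is available — in practice, from the simulator's ground truth — and the
package makes no pretence of estimating $s$ from experimental spectra alone.

## Preprocessing

The scatter effects that particle size imprints on spectra are largely
additive and multiplicative per spectrum, which is why the standard
chemometric corrections help:

* **SNV** — each spectrum standardized to mean 0, SD 1 (sample SD, $n-1$).
* **MSC** — each spectrum regressed on a reference spectrum ($x \approx a + b
  \cdot \mathrm{ref}$) and corrected as $(x - a)/b$. The reference is the mean
  **calibration** spectrum; validation spectra are corrected against the
  calibration reference, never their own.
* **EMSC** — MSC extended with a wavelength polynomial (order 2 by default,
  on the wavelength axis rescaled to $[-1, 1]$); order 0 reduces exactly to
  MSC. No analyte-spectrum terms are included.
* **SG9 / 1D+SG / 2D+SG** — nine-point Savitzky-Golay smoothing and smoothed
  first/second derivatives, computed in a single convolution pass
  (polynomial order 2 for smoothing and first derivative, 3 for the second),
  with derivative outputs scaled per nm. Edges are handled by evaluating the
  boundary windows' fitted polynomials, so spectra keep their length and
  wavelength alignment. A single-pass smoothed derivative is used rather
  than differencing after smoothing; the two agree in the interior but the
  single pass has fewer edge artifacts.
* **NORM / BASELINE** — unit-vector normalization (also max and area modes)
  and linear detrend (also offset mode). Both are defined here since no
  universal convention exists; both are configurable.

All operators preserve the matrix shape and wavelength grid, and all row-wise
operators are leakage-free by construction. For MSC/EMSC the fitted state is
learned from calibration rows only, and applying a state never mutates it.

## Splitting, PLS, and model selection

`kennard_stone_split()` is the deterministic maximin selection: seed with the
most distant pair, then repeatedly add the sample maximizing its minimum
distance to the selected set; ties go to the smallest row index. Distances
are computed on the raw absorbance spectra, and the same split is reused for
every preprocessing method, so method comparisons share
calibration/validation membership and are not confounded by split variance.
The default calibration share is 2/3.

`pls_fit()` is NIPALS PLS on mean-centered spectra and response — centering
only, no variance scaling, the usual convention for spectra. With a
univariate response the NIPALS weight per component is available in closed
form, so no inner iteration (and no convergence tolerance) is needed. The
sequential components are collapsed into a single regression vector
$b = W (P^\top W)^{-1} q$. Successive score vectors are mutually orthogonal;
this is asserted in the tests rather than assumed.

Model size is chosen by leave-one-out cross-validation: `loocv_press()`
refits on each $n-1$ subset, accumulates PRESS per latent-variable count,
and selects the PRESS minimum with ties broken toward fewer latent
variables. LOO is per sample (not per batch), and preprocessing is applied
once per method before the CV loop: the MSC/EMSC reference therefore sees
all calibration rows during CV, a small, documented leakage internal to the
calibration set (validation rows are never involved). Folds that exhaust
their numerical rank simply stop growing and carry their last model forward,
which leaves PRESS flat beyond the rank — relevant for noise-free synthetic
data.

`evaluate_model()` reports RMSEC/RMSECV/RMSEP, $R^2$ values computed as
$1 - SS_{res}/SS_{tot}$ against each set's own mean (not squared
correlation — conventions differ, so the definition is fixed here), and
RPD $=$ SD(validation references, $n-1$) / RMSEP. A perfect validation fit
yields `Inf`, reported as such rather than dropped.

## The synthetic generator

Because no public dataset accompanies this problem, the package ships a
generator whose defaults emulate the study design it targets: 30 base powder
samples (10 batches × 3), sieved into 7 fractions (355–850 down to <90 μm,
representative diameter = arithmetic mean of the sieve bounds, 45 μm for the
open class), 3 replicate spectra averaged per sample, wavelengths 780–2500 nm.
The default grid step is 2 nm (861 points) — a deliberate desk-scale choice;
the instrument-resolution 0.5 nm grid is one config field away.

Per sample: concentration $c \sim$ Normal(1.5, 0.5) mg·g⁻¹ truncated at 0.2
(magnitudes chosen so that RMSEP in the 0.1–0.3 mg·g⁻¹ range corresponds to
RPD in the 2–5 band typical of this application);
$k(\lambda) = c\,\alpha(\lambda) + b(\lambda)$ with $\alpha$ a sum of three
Gaussian bands (1200, 1700, 2270 nm — second overtone, first
combination-overtone and combination regions) and $b$ a smooth background
rising toward long wavelengths; $s$ from the $1/d$ law with $s_0 = 1$ at
137.5 μm; $R_\infty$ by exact K-M inversion; then per replicate
$R = R_\infty(1 + \varepsilon_{mult}) + \varepsilon_{add}$ clipped to
$(10^{-6}, 1]$, and the replicate absorbances averaged. The multiplicative
error is one scalar draw per replicate spectrum — the packing/gain variation
that scatter correction targets — while the additive error is independent
per wavelength (64-scan averaging is folded into its SD of 5×10⁻⁴).
Reference values get unbiased relative noise with CV 1.5 %, standing in for
the chromatographic assay. Everything is reproducible from one seed, and
`pure_scatter_dataset()` freezes the chemistry so only particle size and
noise vary.

What the generator does **not** emulate: real absorptivity line shapes and
band substructure, wavelength-dependent noise, instrument drift, moisture
and matrix variation between batches, non-ideal sieving (overlapping size
distributions), and any deviation from ideal K-M optics (finite layer
thickness, anisotropic scattering). Passing tests therefore demonstrate that
the pipeline recovers what the K-M generative model puts in — not that any
specific real powder will reach the same figures.

With the default noise levels the synthetic models are cleaner than typical
experimental ones (RPDs around 10 rather than 2–5): the generator's noise
floor is set by the reference-assay CV plus small optical noise, with none
of the unmodelled real-world variation listed above. The *structural*
patterns are the point, and they are the ones asserted in the tests:

```{r study, eval = FALSE}
dat <- simulate_dataset(sim_config(seed = 1))
study <- run_full_study(dat$spectra, dat$references)
```

* coarser fractions show uniformly higher absorbance;
* single-fraction models beat pooled ones at their own fraction (scatter is
  constant within a fraction), and the best model overall is a
  single-fraction one, while pooled models are more homogeneous across sets;
* on every pooled set, the best scatter-correcting method (MSC, SNV or EMSC)
  beats raw spectra — though not every corrector individually: at near-zero
  noise EMSC's extra polynomial freedom can cost accuracy, so the package
  asserts the best-corrector form of the claim;
* the designated pooled model (90–180 μm) cross-predicts at least two of its
  three member fractions as well as or better than those fractions' own
  models (best method on each side, mirroring how such comparisons are
  conventionally tabulated);
* with all noise switched off, every model in the study predicts below
  10⁻³ mg·g⁻¹ RMSEP — the generative model is exactly PLS-learnable, which
  pins any larger error on noise, not on pipeline defects.

## Numerical and design choices

* "Best" model per fraction set = maximal RPD; ties toward fewer latent
  variables, then method order.
* Latent variables are capped at 12 by default (and always at
  $n_{cal} - 2$); PRESS picks within the cap.
* Cross-prediction uses only samples from the pooled model's validation
  partition and refuses anything that touched its calibration — asserted by
  a mutation test: perturbing validation spectra leaves fitted models
  bit-identical.
* Kennard-Stone ties (duplicate rows) resolve by smallest index, not by
  error.
* Degenerate inputs error loudly and name the offender: reflectance outside
  $(0, 1]$, constant spectra under SNV, zero-variance responses, constant
  validation references (undefined RPD).
* Report files are plain TSV; write → read round-trips are exact to well
  below 10⁻¹² relative.

Problem sizes used throughout the package's own tests and in
`scripts/acceptance.R`: the full default dataset (210 samples × 861
wavelengths) for the study-level checks, and a coarsened grid (20–25 nm
step, 12 base samples) for unit-level pipeline checks — sizes chosen as the
smallest that still exercise every code path meaningfully.

## Limitations

The package quantifies one analyte with univariate-response PLS; no
multi-response models, no outlier diagnostics (leverage, Q residuals), no
variable selection, no orthogonal signal correction, and no finite-thickness
or angular K-M variants. The particle-size *response* model (predicting
diameter instead of content) needs no separate machinery: pass
`representative_um` as the response column to the same functions.
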