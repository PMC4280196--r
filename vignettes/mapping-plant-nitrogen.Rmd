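---
title: "Mapping plant nitrogen from Vis/NIR hyperspectral images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping plant nitrogen from Vis/NIR hyperspectral images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypernitro)
```

## The problem

Total nitrogen content (TNC, % of dry matter) governs vegetative growth,
and its spatial distribution across a plant — high in young upper leaves,
low in old stems — is invisible to point measurements such as SPAD
readings or destructive combustion chemistry. Vis/NIR hyperspectral
imaging observes every pixel of a plant organ at hundreds of wavelengths
at once, so a calibration between reflectance spectra and
reference-chemistry TNC can be applied pixel by pixel to *map* nitrogen
rather than merely estimate it.

`hypernitro` implements the full chain for this analysis on cohorts of
leaf, stem and root samples:

1. **reflectance calibration** of raw cubes with white/dark references,
2. **ROI spectrum extraction** and wavelength trimming,
3. **SPXY partitioning** into calibration and prediction sets,
4. **Random-frog wavelength selection** with an embedded PLS submodel,
5. **PLSR calibration** with leave-one-out cross-validation (LOOCV), and
6. **chemical imaging**: pixel-wise application of the fitted linear model.

Because no public instrument data accompany this problem setting, the
package ships a first-class synthetic scene generator that reproduces
the statistical structure the analysis assumes; every stage is tested
against it.

## Models and procedures

### Reflectance calibration

Raw counts are converted per pixel and band as

$$I_{\mathrm{cal}} = \frac{I_{\mathrm{raw}} - I_{\mathrm{dark}}}{I_{\mathrm{white}} - I_{\mathrm{dark}}},$$

treating the white tile as 100% reflectance and the capped-lens dark
frame as 0%. No tile-reflectance correction factor is applied: the
calibration formula as used in practice contains none, and any constant
tile factor would be absorbed into the regression coefficients anyway.
Pixels where white equals dark carry no information; they are marked
invalid (`NA`) and excluded from ROI means and chemical maps, the usual
dead-pixel convention.

### ROI extraction and trimming

The sample spectrum is the arithmetic per-band mean over the ROI mask.
Band trimming keeps the closed interval `[420, 1000]` nm by default —
the ends of the instrument range are noise-dominated. The wavelength
grid is always carried explicitly per band; nothing in the package
relies on band indices, so non-uniform instrument grids pose no
ambiguity. On a uniform 512-band grid over 380–1030 nm the trim retains
456 bands; the number of surviving bands is always data-dependent, never
hard-coded.

### SPXY partitioning

Calibration/prediction splitting uses sample set partitioning based on
joint x–y distances: Euclidean distances on spectra and on the response,
each normalised by its maximum over all pairs, summed, and fed to
Kennard–Stone selection (seed with the farthest pair, then repeatedly
add the sample farthest from the selected set). The procedure is
deterministic; ties break toward the lowest sample index.

Two design choices deserve note:

* **Stratification.** The split runs independently within each organ by
  default. A 280-sample cohort of 120 leaves, 120 stems and 40 roots at
  a 75% fraction then yields exactly 210 calibration samples
  (90/90/30) — the canonical proportional counts. Whether the original
  protocol stratified is not documented; the exact proportionality of
  those counts motivates the default, and a global mode is provided.
* **Quota rounding.** `round(fraction * n)` with half-counts rounded
  toward calibration, which reproduces 210/70 exactly at 0.75.

On noise-free synthetic data the joint metric is monotone in the
response, so the calibration set provably brackets the prediction set's
response range; with instrument noise, near-ties at the range boundary
can swap sides by a margin well under 1% of the range. The test suite
asserts both behaviours.

### Random-frog wavelength selection

The selector is a reversible-jump MCMC-style chain over wavelength
subsets with a PLS submodel as its scoring engine. With `p` wavelengths
and current subset $V_t$ of size $Q_t$:

1. draw a candidate size $Q^* \sim \mathcal{N}(Q_t,\ \theta Q_t)$,
   rounded and clipped to $[1, p]$;
2. build a candidate subset $V^*$: if $Q^* < Q_t$, keep the $Q^*$
   variables of $V_t$ with the largest absolute submodel coefficients;
   if $Q^* > Q_t$, pool $\omega (Q^* - Q_t)$ fresh variables drawn
   uniformly from the complement, refit, and keep the top $Q^*$;
3. score $V^*$ by k-fold cross-validated RMSE of the submodel; accept
   outright if not worse than the incumbent, otherwise with probability
   $\eta \cdot \mathrm{RMSE}_{t} / \mathrm{RMSE}^{*} < \eta$.

The selection probability (SP) of a wavelength is the fraction of
iterations containing it, averaged over independent runs; wavelengths
are ranked by SP (ties toward the lower wavelength). Defaults follow
standard practice: $T = 10{,}000$ iterations, $Q = 50$, $\theta = 0.3$,
$\omega = 3$, $\eta = 0.1$, 50 runs.

Choices made where the published framework leaves latitude:

* the candidate-ranking criterion (absolute PLS coefficients) and the
  worse-candidate acceptance probability
  $\eta \cdot \mathrm{RMSE}_t/\mathrm{RMSE}^*$ follow the cited
  framework's structure, with $\eta$ acting as the stated upper bound;
* the chain-internal error is 5-fold CV RMSE rather than LOOCV — LOOCV
  inside $T \times \mathrm{runs}$ iterations buys nothing but cost;
* the submodel's component count is
  $\min(|V|,\ \texttt{submodel\_max\_lvs},\ n_{\mathrm{train}} - 1)$
  with a cap of 10;
* out-of-range size proposals are clipped, not re-drawn;
* all runs consume one seeded RNG stream, so a single master seed fixes
  the entire result;
* the number of retained wavelengths `k` is always explicit — no
  automatic elbow detection. Typical choices for this problem are 10
  (leaf), 9 (stem), 7 (root) and 8 (whole-plant).

One behaviour worth knowing: with the acceptance probability capped at
$\eta$, the chain under a pure-noise response ratchets toward small
subsets and parks on accidental ones, so single-run SP vectors are
spiky even without signal. Which wavelength tops the null ranking is
arbitrary and unreproducible across seeds, and its SP stays clearly
below what a genuinely informative band attains; run-averaging (the
50-run default) damps but does not remove the spikes. Rankings should
be read jointly with replicate agreement, never from one run.

### PLSR and evaluation

The regression core is mean-centered PLS1, computed with the kernel
form of the NIPALS sequence (algebraically identical for a single
response): weights, loadings and the regression-coefficient path are
built from the centered cross-products $X^\top X$ and $X^\top y$ at
$O(p^2)$ per component, independent of $n$ — this is what makes
thousands of submodel fits inside the frog chain affordable. No
autoscaling is applied; reflectance bands share units and scale.

The latent-variable count is chosen by LOOCV: the RMSECV curve
minimiser, ties toward fewer components, with a default cap of 20.
Models are reported as R/RMSE triads — calibration
($R_C$, RMSEC), cross-validation ($R_{CV}$, RMSECV) and prediction
($R_P$, RMSEP) — where R is the Pearson correlation between predicted
and measured values, reported as 0 with a degeneracy flag when either
side has zero variance. `full_vs_selected_report()` fits the
full-spectrum model (F-PLSR) and the model on the top-`k` frog
wavelengths (RF-PLSR) side by side and reports the triads plus the
variable-elimination percentage $100 (p - k)/p$ (460 → 8 wavelengths
eliminates 98.26%).

Every fitted model carries its explicit linear form

$$\hat{Y}_{\mathrm{TNC}} = b_0 + \sum_i b_i\, R(\lambda_i),$$

which the latent form reproduces to numerical precision (an asserted
invariant), and which is what gets applied per pixel.

### Chemical imaging

`predict_map()` evaluates the linear form at every ROI pixel, matching
model wavelengths to the nearest cube band (an error if farther than
one grid step — selected wavelengths are grid points of the training
table, so any larger discrepancy signals a wrong cube). Predictions are
deliberately **not** clipped to a physical range by default; clipping
is available but off, since raw per-pixel predictions are the honest
output of a linear model. By linearity, the ROI mean of the map equals
the model's prediction of the ROI mean spectrum exactly — a second
asserted invariant.

Rendering uses a linear blue→cyan→yellow→red ramp with exact endpoint
colours at the scale bounds, grey for nodata, and per-organ scale
bounds by default: leaves, stems and roots occupy disjoint TNC ranges,
and a shared global scale would flatten within-organ contrast (a global
mode exists).

## The synthetic scene generator

`scene_config()` defines the study conditions; `generate_scene()` and
`simulate_spectra_table()` realise them reproducibly from a single
seed.

**What it emulates.** Each sample is an image tile with an organ-shaped
ROI (ellipse for leaves/roots, vertical strip for stems) on a bright
board-like background. Pixel reflectance is built as

* an organ-specific smooth baseline continuum — green-vegetation shape
  with a red edge near 705–715 nm and a water dip near 965 nm for
  leaves and stems; a flat, slowly rising soil-like continuum for
  roots;
* minus Gaussian absorption bands (defaults near 550, 650, 760 and
  970 nm) whose depths scale *linearly* with the pixel's TNC;
* times a per-pixel log-normal scatter factor (s.d. 0.03);
* plus additive noise (s.d. 0.005 reflectance units);

and is then "un-calibrated" into a raw/white/dark count triplet
(white ≈ 3000 counts with a mild sinusoidal column pattern, dark ≈ 100
counts) that the calibration formula inverts exactly.

Sample-level TNC draws use truncated normals inside fixed per-organ
envelopes (leaf 2.264–4.871%, stem 0.556–2.135%, root 0.847–1.470%),
with position-level means and spreads expressed as fractions of the
envelope so that organ means order leaf > root > stem and
upper > middle > lower within leaves and stems. The within-sample TNC
field is a smooth gradient (long-axis for stems, radial blade field for
leaves with a midrib ridge on lower leaves) with amplitude 10% of the
sample mean — a free parameter: within-sample nitrogen variance is not
documented for this setting, and 10% was fixed once as a plausible
physiological contrast, not inferred.

**What it does not emulate.** Radiometric detail of any real camera,
petiole/stem morphology, specular highlights, the non-uniform
instrument wavelength grid, soil adhesion on roots, and — most
importantly — any *nonlinearity* between TNC and absorption. Passing
tests therefore demonstrate that the pipeline's machinery is correct
and well-conditioned, not that real pepper-plant spectra are this
predictable: on the generator's linear world, whole-plant RF-PLSR
reaches $R_P$ near 1.0, comfortably above the ≥ 0.85 magnitude the
published benchmark motivates, whereas real tissue yields ≈ 0.88.

## Numerical choices

* PLS component extraction stops when the residual covariance norm or
  score variance falls below `1e-12` relative to its starting value;
  the coefficient path is padded with the last valid solution and the
  fit warns about rank deficiency.
* A constant response yields a flagged intercept-only model rather than
  an error; correlations on zero-variance vectors report 0 with a
  degeneracy flag.
* Kennard–Stone and SP ties break toward the lowest index / lowest
  wavelength — determinism everywhere.
* All stochastic entry points restore the caller's RNG state, so
  user-level `set.seed()` is never silently consumed.
* ENVI I/O supports data types 2/4/5 (int16, float32, float64) in
  BSQ/BIL/BIP interleaves, little- or big-endian, with strict header
  validation against file size.

## Problem sizes used in the tests

The suite runs at deliberately compact sizes chosen to exercise every
code path: tiny cubes (≤ 16×16 px, ≤ 64 bands) for I/O and imaging
oracles; the full 280-sample cohort at a compact grid for the split
counts; frog recovery at 100 samples × 100 bands with 500-iteration,
5-run chains over 50 seeds; and ten full-cohort pipeline replicates at
456 bands with reduced frog settings for parameter recovery. The
reduced `pipeline_config(profile = "reduced")` (24/24/12 samples,
500 iterations, 5 runs) is the same trade-off packaged for interactive
use; `profile = "paper"` restores the full 280-sample, 10,000-iteration,
50-run protocol.

## Known limitations

* PLS1 only — a single response; no multi-response PLS2.
* No spectral pre-processing variants (SNV, MSC, derivatives); the
  design models raw reflectance, and the generator's scatter is mild
  enough that this is the right default. A pre-processing hook would be
  the first extension for real data.
* The frog chain's null behaviour (spiky single-run SP) is inherent to
  the capped acceptance rule; interpret rankings via run averages.
* `generate_scene()` holds all cubes in memory; use
  `simulate_spectra_table()` for large cohorts.
* The ENVI writer emits the header fields this pipeline needs, not the
  full header vocabulary.
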