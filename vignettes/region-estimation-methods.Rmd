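---
title: "Methods: cystic region estimation and observer variability on thyroid ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cystic region estimation and observer variability on thyroid ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonocyst)
```

## The problem

On B-mode ultrasound a thyroid nodule is a mixture of two compartments: an
echoic, speckle-textured *solid* part and a hypoechoic, fluid-filled
*cystic* part. The solid-to-cystic ratio matters clinically — a larger
solid fraction raises malignancy suspicion, a larger cystic fraction argues
for benignity and changes radioiodine planning — yet the ratio is usually
eyeballed, and readers of different experience disagree substantially.
`sonocyst` implements a decision-support quantification of the cystic
percentage from image texture, plus the statistics used to compare such a
system against human readers, and a synthetic phantom generator that makes
the whole chain testable end to end without patient data.

## The texture feature core

The unit of classification is a square patch of 20 × 20 pixels. At the
default pixel spacing of 0.2648 mm/px this is a 5.296 × 5.296 mm footprint;
the spacing is a configuration value (`run_config()$pixel_spacing_mm`), and
the patch side and stride (defaults 20 and 10 px, i.e. 50 % overlap) are
likewise configurable. Patches are laid on a stride grid over the nodule
mask's bounding box and kept when at least `min_inside_fraction` (default
0.8) of their pixels fall inside the nodule; the threshold trades boundary
contamination against patch count.

Each patch is converted to one-dimensional signals so that parametric
signal models can describe its texture. Four scan directions are used —
row-major, column-major, and two zig-zag diagonal scans (over
anti-diagonals and over main diagonals) — giving four length-400 signals,
each a permutation of the same pixel multiset. Directional scanning lets
anisotropic texture show up as differences between the four fits.

Every signal is split into three frequency bands, low [0, 0.05], mid
(0.05, 0.20] and high (0.20, 0.5] cycles/sample, by a zero-phase brick-wall
band-pass implemented as an FFT bin partition: each Fourier bin belongs to
exactly one band, so the three bands reconstruct the signal *exactly* and
energy is conserved bin by bin. This choice (over an IIR filter bank) makes
the reconstruction and Parseval properties exact rather than approximate
and has no phase distortion or edge transient. The band edges separate
echo-level content (DC and very slow trends — the low band deliberately
retains the patch mean, so echogenicity itself remains a feature),
macro-texture, and speckle-scale grain; they are configuration constants.

Each band is summarised by an autoregressive model of order 2 fitted with
Burg's method, which minimises the summed forward and backward prediction
error, is stable on short records, and yields reflection coefficients
bounded by one so the fitted model is stationary for well-conditioned
input. The features per (signal, band) are the two AR coefficients and
`log(residual_variance + 1e-12)`; the epsilon floors the logarithm for
degenerate (zero-variance) bands, which by convention return zero
coefficients and zero residual variance. In total 4 signals × 3 bands ×
3 values = **36 features per patch**, in a fixed signal-major, band-minor
order pinned by a feature-layout version string embedded in trained models.

Why these features discriminate: speckle is well approximated as
multiplicative noise, so its local variance scales with the squared echo
level. A cystic patch is dark and nearly structureless — small residual
variances in every band — while a solid patch is bright and textured. The
log-residual-variance features carry most of the separation; the AR
coefficients add sensitivity to texture correlation structure.

## Classification and aggregation

Patches are labelled for training from the phantom truth by majority: a
patch is *cystic* when more than half of its in-nodule pixels are cystic.
A random forest (200 trees, default mtry) is the classifier; the model
family is fixed but every hyperparameter sits in `run_config()`. Training
and evaluation are seeded and deterministic.

Accuracy is always reported under **grouped cross-validation with nodules
as groups**: all patches of a nodule stay in the same fold, so a nodule is
never classified by a forest that saw its own patches. The nodule-level
cystic percentage is the patch-count ratio
`100 · n_cystic / n_patches` (the solid percentage is its complement);
pixel-weighted aggregation would be a straightforward variant but the
patch-count rule is the primary, simplest reading of classifier-output
aggregation. In `recover_cystic_suite()` the per-nodule estimates are
formed from out-of-fold predictions only.

## The synthetic phantom generator

No image data accompany the published comparison, so the generator defines
the package's study conditions:

* **Speckle**: fully developed speckle approximated as unit-mean
  gamma-distributed multiplicative noise (shape `speckle_shape`; relative
  variance `1/shape`) on a constant echo level, followed by a Gaussian
  point-spread blur. The blur sigma is taken from the background
  parameters for the whole frame, because the point-spread belongs to the
  imaging system, not to the tissue compartment.
* **Nodule geometry**: an ellipse that must fit the frame; the cystic
  compartment is the union of 1–3 random ellipses grown or shrunk by
  bisection on a common scale factor until the realised area fraction is
  within ±0.02 of the requested `cystic_fraction_true` (an error names the
  achieved fraction when the geometry cannot reach the target).
* **Echogenicity defaults**: background level 0.35 (shape 6), solid 0.60
  (shape 4), cystic 0.08 (shape 8) — the hypoechoic-cyst convention; the
  published study gives no intensity statistics, so these are calibrated
  only by that qualitative convention and by giving a realistic, clearly
  visible but noisy contrast.
* **Annotators**: a reader is a smooth radial jitter of the true boundary
  (four random harmonics with RMS amplitude `boundary_jitter_px`; zero
  jitter returns the truth exactly) plus a reported cystic percentage =
  truth + bias + Gaussian noise, rounded to a 5-point step (the granularity
  dominant in published per-nodule estimates) and clipped to [0, 100]. The
  default panel is one experienced reader (jitter 1.5 px, no bias, SD 4)
  and two less experienced readers (jitter 3–3.5 px, biases ±6, SD 9–11),
  emulating an experience-dependent panel.

The default suite is 20 nodules on 224 × 224 frames with true cystic
fractions on an even 10–90 % grid — sized so the full pipeline (about 1 200
patches) runs in seconds while giving every composition category support.
What the phantoms deliberately do **not** model: attenuation and shadowing,
acoustic enhancement behind cysts, wall echoes and septations, calcifications,
anisotropic point-spread, 3-D geometry. Passing the recovery tests therefore
shows the method is internally coherent and recovers known composition under
idealised speckle — not that it reaches the same accuracy on clinical images.

## Ground-truth averaging of annotator masks

Multi-annotator fusion follows the area-averaging rule: the consensus mask's
area equals the mean of the annotators' mask areas. Re-binarising a mean
area needs a spatial rule; the package thresholds the pixelwise mean of the
masks over its distinct levels, which yields nested superlevel sets whose
areas bracket the target, and then fills from the critical (tied) level —
nearest to the consensus centroid first, row-major tie-break — until the
rounded target area is met. With only a few annotators the distinct levels
alone are too coarse to realise the mean area (three nested masks admit
only three superlevel areas), so the partial fill is what guarantees the
area property to within one pixel while still never including a pixel
before another one that more annotators agreed on. Pairwise-disjoint
annotator masks are rejected outright: a silent empty consensus would
poison every downstream statistic.

## Observer-variability statistics

The per-nodule disagreement statistic is the **variance percentage**
`(obs1 − obs2)/obs1 × 100`, with obs2 the constant decision-support reading.
Conventions: `obs1 = 0 < obs2` has no defined deviation and returns `NA`;
`obs1 = obs2 = 0` is zero deviation and returns 0. The published table is
internally inconsistent on the second case (two 0/0 cells print NA while
four print 0); the package applies 0/0 → 0 uniformly and *flags* the two
discrepant printed cells rather than matching them. Printed-style rendering
truncates toward zero at one decimal (two as an option), matching the mixed
precision of the published table; reproduction is checked at |Δ| ≤ 0.1 on
raw values so the truncation convention cannot mask a real error.

The **classification match percentage** needs a composition categorisation,
which the published analysis does not disclose. The default scheme bins the
cystic percentage at 10/50/90 into solid, predominantly solid, predominantly
cystic, cystic — standard ultrasound composition vocabulary — with boundary
values assigned to the upper bin; the scheme is an explicit argument
everywhere, and the published match percentages are *reported* under the
default scheme, never asserted as reproduced. The all-observer statistic is
ambiguous in its published wording, so both readings are computed: the
fraction of nodules on which every reader and the reference agree
(primary), and the mean of the per-reader match percentages.

The significance test is an uncorrected Pearson chi-squared on the
observers × categories table of category counts, df = (r−1)(c−1);
unrealised categories are dropped, and a single-category table returns the
defined degenerate result (statistic 0, p = 1) with a warning. The
construction is documented and swappable since only the test family, not
the table, is published.

## Numerical and degenerate-input choices

* Seeded determinism throughout: every stochastic function takes a seed and
  restores the caller's RNG state; identical arguments give identical output.
* Zero-variance AR input → zero coefficients, zero residual variance; the
  log-variance floor is `log(1e-12)`.
* Empty mask → zero area; two empty masks → overlap 1.0 by convention;
  empty patch list → estimation error (there is nothing to aggregate).
* Composition conservation (solid + cystic = nodule pixel count) and the
  echogenicity ordering (cystic mean < solid mean) are asserted per
  generated phantom in the test suite.

## Acceptance surface

The analysis's own acceptance surface on the default suite is: grouped CV
patch accuracy ≥ 0.85 and nodule-level MAE ≤ 10 percentage points, plus
exact reproduction of the published variance-percentage table from the
packaged observer table. The patient-level match percentages and p-value
depend on the undisclosed composition scheme and on patient data, so they
are computed and reported under the default scheme but not asserted.

## Known limitations

Patch-count aggregation is biased at extreme compositions (a thin solid rim
contributes few qualifying patches), which is visible as a mild
overestimation at high cystic fractions in the recovery table; the
tolerance above absorbs it. The phantom's idealisations listed earlier mean
clinical performance claims require clinical data. The four-scan,
three-band, order-2 construction is one defensible instantiation of a
patch-to-signal AR feature pipeline; scan set, band edges and order are all
isolated in configuration so alternates can be swapped in.
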