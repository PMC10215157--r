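---
title: "Methods: segmentation, shape statistics and exhaustive linear-classifier search for hepatocyte vacuolar degeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying vacuolar degeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`vacuoquant` quantifies vacuolar degeneration (VD) — hydropic swelling of
hepatocytes that appears as near-white "holes" in H&E liver sections — and
asks which region-shape features separate treatment groups. This vignette
documents the model and every numerical decision a maintainer or reviewer
would want to audit: what each stage assumes, which parameters matter,
what the synthetic generator does and does not emulate, and where the
design was genuinely open.

## 1. Segmentation model

Lesions are *white in all three RGB channels*, which distinguishes them
from the pink eosin background (dark in green) and the purple hematoxylin
nuclei (dark everywhere). The chain is:

1. **Exclusion masking.** Manual masks cover sinuses and central veins —
   structures that are white but are not lesions. Excluded pixels are
   removed *before* histogram computation, not just from the output:
   a large vein would otherwise distort both the contrast quantiles and
   the Otsu threshold. This is the stricter of the two possible readings
   and the one consistent with the masks' purpose.
2. **Contrast stretch.** Each channel is linearly rescaled so that its
   `p` and `1 − p` quantiles (default `contrast_saturation = 0.01`) map to
   0 and 255, clipping outside, rounding to nearest. A constant channel is
   passed through unchanged. The stretch standardises exposure across
   images; any fixed monotone alternative would do, but a quantile stretch
   is robust to the handful of saturated pixels real cameras produce.
3. **Otsu binarization at half level.** The 256-bin Otsu level `t*` of
   each channel maximizes between-class variance over all cuts `b + 0.5`
   (`b = 0..254`); tied cuts — common when the histogram has an empty gap
   between tissue and white — are averaged, so `t*` may be fractional.
   Foreground is `intensity >= otsu_scale * t*` with `otsu_scale = 0.5` by
   default; `otsu_scale = 1` recovers plain Otsu. The half-level rule reads
   a "50% of the Otsu threshold" binarization literally; because the white
   class sits far above the tissue mode, lesion recovery is insensitive to
   the factor over a wide range, and the factor is exposed as a parameter
   precisely because the alternative reading (binarize at fixed level 0.5
   after normalisation) cannot be excluded.
4. **Fusion.** Channel masks are combined with logical AND (default):
   white requires *all* channels bright. OR is available by configuration.
   A degenerate (constant) channel contributes no white evidence — its
   channel mask is empty, so AND fusion yields an empty mask (with a
   warning when all three channels are degenerate). This conservative
   choice means a blank, constant image segments to zero lesions rather
   than to one giant region.
5. **Small-object removal.** Components (8-connected by default) with
   fewer than `min_region_area = 10` pixels are discarded; area exactly 10
   is kept. Below ~10 px the chain-code perimeter and the moment ellipse
   are dominated by discretization (a single pixel has no traceable
   boundary at all), and camera noise reliably produces a few isolated
   above-threshold pixels.

**Invariants** (enforced by tests): the final mask is contained in the
fused mask, which is contained in the non-excluded support
(anti-extensivity); every retained component has area ≥ 10; lowering
`otsu_scale` never removes fused foreground.

## 2. Shape descriptors and the ten predictors

Per region: area `A` (pixel count); perimeter `P` as the chain-code length
of the outer boundary (Moore tracing; axial steps weigh 1, diagonal √2);
major axis length (MAL) and eccentricity of the ellipse with the same
normalized second central moments as the pixel set; circularity
`C = 4πA/P²`. Per image, the ten predictors in fixed order: mean and
sample SD (n−1) of area, perimeter, MAL, eccentricity, circularity.

Numerical choices:

* **+1/12 variance correction.** Treating each pixel as a unit square adds
  1/12 to both coordinate variances. A single-pixel row then has a
  positive minor axis and eccentricity stays strictly below 1, keeping the
  `[0, 1)` invariant without special-casing thin regions.
* **Chain-code perimeter.** The estimator is stated in the output
  metadata because circularity depends on it. It reproduces the familiar
  behaviour of MATLAB-style `regionprops` perimeters: discretized discs
  score circularity ≈ 0.93–1.05. It is *not* scale-homogeneous under
  nearest-neighbour upsampling: a diagonal step (√2) becomes a two-pixel
  staircase (2 + √2), so doubling a diagonal-rich region multiplies the
  perimeter by up to 2.41, not 2 — a property of the blockier upsampled
  shape itself, shared by all local boundary-length estimators. The scale
  property test asserts the exact staircase bounds rather than a naive
  factor 2.
* **Degenerate regions** (boundary untraceable, i.e. single pixels) raise
  an error rather than returning `NaN`s; the small-object filter removes
  them upstream in normal operation.
* **Zero- and one-lesion images.** An image with no regions keeps its row
  in the predictor table as an all-zero vector flagged `no_lesions` — it
  still carries class information for the lesion-presence schemes. A
  single-region image gets SD components 0 and a `single_lesion` flag,
  rather than being dropped, so the study design stays intact.

## 3. Group statistics

Pooled estimators are computed across *regions*, not across image means:
a 32-image cohort yields only 32 per-image means but hundreds to thousands
of regions, and the region-level distribution is what the lesion-size
biology lives in. Anderson–Darling (one-sample, estimated mean/variance,
small-sample modification `A*² = A²(1 + 0.75/n + 2.25/n²)`) checks whether
parametric modelling of the pooled distributions is defensible; in
practice it is not — lesion areas are heavy-tailed — which motivates the
nonparametric two-sample Kolmogorov–Smirnov comparisons of the control
group against each treatment group, per measure, with asymptotic p-values
(region counts are large; no exact small-sample enumeration). No
multiple-testing correction is applied; p-values are labelled raw. The AD
variant (one-sample vs k-sample) was an open choice; one-sample normality
is what justifies abandoning distribution modelling, so that is what is
implemented. Which variable the tests target was equally open: they are
run on all five measures and reported as a table.

## 4. Exhaustive linear-classifier search

With 32 cases and 4 classes, anything beyond a linear discriminant
overfits, and even the linear model cannot be cross-validated credibly.
The package therefore treats the classifier as a *descriptive* instrument:

* **Model.** Two-class Fisher LDA with pooled within-class covariance,
  ridge-regularized by `λ·trace(Σ)/p`, `λ = 1e-6` — just enough to make
  singular covariances (p up to 10, n = 32) solvable without measurably
  moving any boundary. Empirical class priors; score ties go to the class
  listed first in the scheme.
* **Protocol.** Resubstitution accuracy by default — the only protocol
  consistent with reporting a perfect score on linearly separable data —
  with leave-one-out available and labelled distinctly. Resubstitution
  numbers describe separability of *these* cases; they are not estimates
  of generalization error, and the reports keep the `eval` column so the
  two are never conflated.
* **Search.** All `2^p − 1` non-empty subsets (1023 for the full ten), in
  five schemes: one-vs-rest per group; common predictors (one shared
  subset, scored by the arithmetic mean of the four one-vs-rest
  accuracies); control vs each treatment pair; lesion presence on all
  images; control vs merged treatments on lesion-positive images only.
  Results are sorted (accuracy desc, size asc, bitmask asc); the best-
  subset report lists *all* subsets tied at maximal accuracy and minimal
  size, because on small samples the tie set is itself informative; and
  the Pareto front of (accuracy, subset size) summarises the
  accuracy-vs-parsimony trade-off. Mean-only or SD-only searches are the
  same call with a restricted `predictor_set`.

## 5. The synthetic-histology generator

No slides accompany studies of this kind, so the generator defines the
study conditions under which everything is tested:

* **Design.** 6 CONTROL, 10 TMG, 9 CMG, 7 CEG images (the group sizes of
  the emulated cohort), canvas 964×1286 px — half the emulated camera
  frame (1928×2572), keeping default runs fast; full size is one
  configuration field away.
* **Lesions.** Ellipses with areas drawn from a log-normal *truncated at
  10 px²* and moment-matched so that the truncated mean/SD equal the
  per-group calibration targets (CONTROL 88.49/231.74, TMG 99.15/91.91,
  CMG 77.36/73.35, CEG 140.11/402.51 px²). Truncation matters: pooled
  estimators of real cohorts are computed *after* small-object removal,
  so calibrating an untruncated distribution would lose ~20% of lesions
  to the filter and bias the measured mean upward by ~25%. Axis ratios
  (minor/major) are truncated normal with means ≈ 0.63 — the ratio implied
  by pooled eccentricity ≈ 0.78 — and group-specific spreads; orientations
  uniform; an optional low-amplitude two-harmonic radial roughness keeps
  circularity near 1, consistent with the calibration targets. Lesion
  counts per image are uniform on 5–60 (no cohort-level value exists for
  this; the range covers sparse to florid fields), and each image shows
  lesions at all with the group's VD frequency (50%, 90%, 75%, 66% for
  CONTROL/TMG/CMG/CEG). Placement is rejection sampling with
  bounding-circle non-overlap, erroring after 1000 retries per lesion.
* **Background.** Pink eosin base RGB (235, 105, 185) with independent
  per-channel Gaussian texture (SD 8), dark nucleus blobs
  RGB (120, 85, 150), and — essential — **sinusoid specks**: thin
  near-white blobs of 4–7 px on a jittered 14 px grid (~3% of the canvas,
  comparable to the sinusoid fraction of real liver fields). Each speck is
  below the 10 px² filter, so specks never enter the lesion statistics,
  but collectively they anchor the white intensity class: they hold the
  upper contrast quantile at white and give Otsu a white mode to cut
  against even on lesion-free images, exactly the role sinusoids play in
  real sections. The background green level is deliberately close to the
  nucleus green level so that the between-class variance of the
  tissue-vs-white split dominates the nuclei-vs-tissue split on the green
  channel; the palette is otherwise cosmetic and has no effect on ground
  truth.
* **Vein.** One large white ellipse (radius ~55–100 px, shrunk if the
  canvas is crowded) fully covered by an exclusion mask dilated by a 5 px
  margin, as a human annotator would draw it — so the masking path is
  exercised by every default image.
* **Determinism.** A master seed fans out to per-image child seeds via a
  stable string hash of (stage, group, index): identical configs are
  byte-identical, and adding images to a config never changes existing
  ones.

**What the generator does not emulate:** optical blur and chromatic
aberration, staining gradients, touching/confluent vacuoles, lipid vs
hydropic vacuole subtypes, tissue tears, and focal debris. Passing tests
therefore demonstrate that the pipeline recovers known geometry under
controlled noise — not that segmentation is robust to every real-world
artifact; on real slides the exclusion masks and the `otsu_scale`
parameter are the operator's levers.

## 6. Problem sizes used in the test and acceptance runs

Unit and property tests run on canvases of roughly 200–500 px and datasets
of 4–6 images — large enough that every lesion is measurable and every
property bites, small enough to iterate quickly. The dataset-shape check
uses the full 32-image default design. The separability experiment
(10 + 10 images, default canvas) plants CONTROL lesions at the packaged
calibration against TMG lesions at area 2000 ± 400 px² with all images
lesion-positive, giving a mean-MAL separation of ~20 pooled SDs — far past
the ≥ 5 SD condition it asserts — and the exhaustive paired search then
attains 100% resubstitution accuracy, the expected outcome for linearly
separable shape profiles.

## 7. Known limitations

* Resubstitution accuracy flatters: with 10 predictors and 32 cases, many
  subsets fit noise. The tie sets and Pareto fronts make this visible but
  do not cure it; treat selected subsets as hypotheses.
* The AND fusion assumes lesions are achromatic white. Strongly tinted
  vacuoles (e.g. bile-stained) would need OR fusion or per-channel scales.
* The chain-code perimeter, like all local estimators, carries a
  systematic orientation-dependent bias of a few percent; circularity
  comparisons are therefore only meaningful within a fixed estimator.
* KS p-values are asymptotic and ignore the within-image correlation of
  regions; they describe distribution differences, not image-level
  significance.
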