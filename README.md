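# vacuoquant

Digital quantification of **vacuolar degeneration (VD)** in hematoxylin–eosin
(H&E) stained liver micrographs.

VD — hydropic swelling of hepatocytes — shows up in H&E sections as
near-white, roughly elliptical "holes" in the pink cytoplasm. Pathologists
grade it visually; `vacuoquant` measures it. The package is aimed at groups
comparing liver morphology across treatment arms (e.g. drug-toxicity studies
with a control group and several protocol groups) who want reproducible,
per-lesion shape statistics and an honest answer to the question *"which
shape features separate the groups?"* on cohorts far too small for modern
machine learning.

## What it computes

1. **Segmentation.** Each RGB micrograph (optionally with a manual exclusion
   mask covering sinuses/central veins, which are white but not lesions) is
   processed as: per-channel quantile contrast stretch → per-channel Otsu
   binarization at `otsu_scale × t*` (default 0.5, computed on non-excluded
   pixels) → logical AND fusion across channels (white = bright in R, G and
   B) → removal of connected components below 10 px².
2. **Shape descriptors.** For every remaining 8-connected region: area *A*
   (px²), chain-code perimeter *P* (axial steps 1, diagonal √2), major axis
   length (MAL) and eccentricity *e* of the ellipse with identical
   normalized second central moments (with the +1/12 pixel-variance
   correction), and circularity *C* = 4π·A/P². Per image, the **ten
   predictors**: mean and sample SD of each of the five measures.
3. **Group statistics.** Pooled per-group estimator tables (all regions of a
   group pooled), Anderson–Darling normality checks, and two-sample
   Kolmogorov–Smirnov comparisons of the control group against each
   treatment group, per measure.
4. **Exhaustive classifier search.** A pooled-covariance Fisher linear
   discriminant (ridge 1e-6 for solvability) is fitted on **every one of the
   2¹⁰ − 1 = 1023 non-empty predictor subsets**, in five schemes:
   one-vs-rest per group, a common-predictors scheme scored by the average
   of the four one-vs-rest accuracies, control-vs-each-treatment pairs,
   lesion presence on all images merged, and control vs merged treatments on
   lesion-positive images. Reports list all subsets tied at the best
   (accuracy, minimal size) and the Pareto front of accuracy vs subset size.
5. **Synthetic histology.** Because such studies rarely deposit slides, a
   seeded generator renders H&E-like micrographs — pink textured background,
   dark nuclei, thin white sinusoid specks, white elliptical vacuoles with
   per-group calibrated area/axis-ratio distributions, and an optional white
   vein covered by an exclusion mask — with full ground truth, so the whole
   pipeline is testable end to end.

## Worked example

```r
library(vacuoquant)

prof  <- group_profile("TMG")                     # packaged calibration
specs <- sample_vacuoles(prof, 40, canvas = default_canvas(), seed = 1)
rec   <- render_image(specs, with_vein = TRUE, seed = 2, group = "TMG")
mask  <- segment(rec)
mask
#> <vq_lesion_mask> 964x1286, 40 components, 4003 foreground px
#>   thresholds (RGB): 55, 70.75, 80.75

reg <- describe_regions(mask, image_id = "TMG_demo")
head(reg, 3)
#>   image_id region_id area perimeter    mal eccentricity circularity
#> 1 TMG_demo         1  239     57.70 22.124       0.7806      0.9022
#> 2 TMG_demo         2   98     35.80 13.838       0.7522      0.9609
#> 3 TMG_demo         3   52     24.49  9.692       0.6993      1.0899

round(unlist(image_summary(reg, "TMG_demo", "TMG", TRUE)[predictor_names()]), 3)
#>         mean_area           sd_area    mean_perimeter      sd_perimeter
#>           100.075            85.926            33.408            14.324
#>          mean_mal            sd_mal mean_eccentricity   sd_eccentricity
#>            13.328             5.212             0.767             0.036
#>  mean_circularity    sd_circularity
#>             1.021             0.102
```

All 40 planted vacuoles were recovered as 40 segmented components; the
per-image predictor vector lands on the group's calibration (pooled lesion
area ≈ 99 px², eccentricity ≈ 0.78, circularity ≈ 1).

A full study-shaped run (6/10/9/7 images across CONTROL/TMG/CMG/CEG, all
stages, all five schemes) is one call:

```r
res <- run_pipeline(run_config(), master_seed = 1, out_dir = "run1")
```

which writes images, masks, `regions.csv`, `predictors.csv`,
`pooled_estimators.csv`, `distribution_tests.csv`, the per-scheme search
reports, and a config snapshot making the run byte-for-byte reproducible.
The same stages are available from a shell via the bundled script
(`inst/exec/vacuoquant`), with subcommands `run`, `synth`, `segment`,
`describe`, `stats` and `search`.

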