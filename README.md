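# multicellseg

Segmentation of **multi-cellular regions vs background** in bright field /
DIC microscopy images, and the two quantitative motility assays built on
it: wound-healing kinetics and scatter-assay scoring.

Bright field images show cells as *texture*, not as intensity contrast, so
threshold- and edge-based tools struggle — especially on narrow, almost
healed wounds. `multicellseg` instead treats segmentation as supervised
classification of small image patches:

1. **Patch cascade** — each 20 × 20 px patch is described by five texture
   feature sets (intensity histogram, gradient-magnitude histogram,
   orientation histogram, multi-scale variance, edge/energy measures).
   Five linear SVMs score the sets, a sixth linear SVM stacks the five
   scores; the patch confidence is the signed distance to that combiner
   hyperplane (positive = background, i.e. "non-occupied").
2. **Automatic threshold** — Otsu's criterion on the confidence scores
   (clamped to the SVM zero when the scores look single-class) yields the
   initial patch labeling.
3. **Region classifier** — connected components of background patches are
   re-examined with pooled, region-scale texture features; false wound
   regions are vetoed. The step is monotone: it never creates background.
4. **Graph-cut refinement** — a binary submodular energy (logistic unaries
   from the upsampled confidence, contrast-sensitive Potts pairwise terms,
   hard seeds in the eroded interior of the baseline labeling) is
   minimized exactly by a compiled max-flow solver, giving the final
   pixel-resolution mask.

On top of the masks:

* **Wound healing** — per-frame background area, normalized closure
  curves, OLS healing slopes with Pearson linearity, and treatment
  comparison via median-slope fold-change + Wilcoxon rank sum test
  (exact enumeration for small samples).
* **Scatter assay** — images are downsampled to a common 5 µm/px scale,
  segmented, and summarized by a 10-bin rotation-invariant uniform local
  binary pattern (LBP, P = 8, R = 1) histogram over cellular pixels; a
  linear SVM classifies scattered vs non-scattered under leave-one-out
  and 100-fold constrained split validation.

A calibrated synthetic-image generator (textured cellular regions,
irregular wound boundaries, linearly closing wound series, clustered vs
dispersed scatter phenotypes — all with exact truth masks) makes every
stage trainable and testable without real microscopy data.

## Worked example

```r
library(multicellseg)

# five training images with exact truth, spanning wide to narrow wounds
fracs <- c(0.35, 0.30, 0.25, 0.18, 0.10)
train <- lapply(1:5, function(i) generate_wound_image(
  synth_params(rng_seed = 100 + i, wound_area_fraction = fracs[i])))
model <- train_multicellseg(train, seed = 1)

# segment a fresh image and measure against its truth mask
pair <- generate_wound_image(synth_params(rng_seed = 3))
res <- segment_image(model, pair$image)
res$mask_final
#> <segmentation_mask> 200 x 200 px, stage 'final', background fraction 0.304
pixel_accuracy(res$mask_patch, pair$mask)   # 0.935  (patch stage)
pixel_accuracy(res$mask_final, pair$mask)   # 0.990  (after graph cut)
conf_px <- expand_confidence(res$confidence, dim(pair$image$intensities))
roc_curve(conf_px, pair$mask)$auc           # 0.985

# wound kinetics: a 6-frame series closing at 10% of initial area per frame
series <- generate_wound_series(synth_params(image_size = c(256, 256),
                                             wound_area_fraction = 0.3,
                                             rng_seed = 42), 6, 0.1)
fine <- train_multicellseg(train, seed = 1, patch_size = 10)
masks <- lapply(series, function(p) segment_image(fine, p$image)$mask_final)
fit_healing(wound_area_series(masks, times = 0:5))
#> <healing_fit> slope -0.0981 per time unit, r = -0.9993, p = 7.5e-07, n = 6
```

The fitted normalized-area slope (−0.098 per frame) recovers the
generator's closure rate (0.1), and the near-perfect |r| reflects the
linear closure the series was built with.

A thin command-line front-end wraps the same functions
(`inst/cli/multicellseg.R`; subcommands `synth`, `train`, `segment`,
`evaluate`, `wound`, `scatter`), and `run_config()` /
`write_run_config()` give a flat key=value configuration surface with
fixed documented defaults.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "multicellseg", load_package = "installed")'
```

The suite contains per-module unit tests, property-style invariants
(determinism, monotonicity, gray-scale invariance), and oracle checks:
min-cut labelings against exhaustive enumeration, the LBP descriptor
against a brute-force per-pixel implementation, ROC AUC against the
Mann–Whitney statistic, and the statistical tests against their exact
small-sample enumerations.

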