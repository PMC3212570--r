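---
title: "Segmenting multi-cellular regions in bright field images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting multi-cellular regions in bright field images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicellseg)
```

## The problem

Bright field and DIC microscopy show multi-cellular regions as *textured*
areas against a comparatively smooth background, with little intensity
contrast between the two. Classical wound-healing and scatter assays need
exactly one quantity from such images: which pixels are covered by cells
and which are not. `multicellseg` answers that question with a supervised,
patch-classification pipeline and then builds the two assay analyses on
top of it.

## The segmentation model

The pipeline has four stages.

**1. Patch classification.** The image is tiled with non-overlapping
square patches (20 × 20 px by default). Each patch is described by five
texture feature sets:

* F1 — 16-bin intensity histogram on [0, 1];
* F2 — 16-bin gradient-magnitude histogram (central differences), fixed
  bin edges on [0, √2/2] so features are comparable across images;
* F3 — 8-bin gradient-orientation histogram weighted by magnitude;
* F4 — sample standard deviation of the patch after Gaussian smoothing at
  σ ∈ {0, 1, 2, 4} px (a multi-scale texture-energy profile);
* F5 — edge-pixel fraction (gradient magnitude above the image-global Otsu
  level) and mean absolute Laplacian.

One linear SVM is trained per feature set and a sixth linear SVM — the
*combiner* — stacks the five per-set confidence scores. A patch's final
confidence is the signed Euclidean distance of its standardized
stage-one score vector to the combiner hyperplane; positive means
background ("non-occupied"). The combiner is trained on *out-of-fold*
stage-one scores (2-fold cross-fitting): naive in-sample stacking would
see optimistically separated inputs and learn a miscalibrated second
stage. Class weights are balanced because wound images are mostly
cellular. Training labels come from pixel truth masks by majority: a
patch is background iff more than half of its pixels are.

**2. Automatic thresholding.** The confidence map is cut by Otsu's
criterion applied to the scores themselves. When the score distribution is
single-class (all one sign and unimodal by a dip-free histogram check) the
threshold clamps to the SVM decision boundary at zero — an unsupervised
split inside a single class would hallucinate background in fully
confluent images.

**3. Region reclassification.** Connected components of background-labeled
patches (4-connectivity; 8 would merge diagonal speckle into wounds) are
re-examined by a separate linear classifier whose features pool over the
whole component: log area, confidence statistics, a pooled
gradient-magnitude histogram, pooled multi-scale standard deviations, and
solidity on the patch grid. A grouped region carries far more textural
evidence than any single patch, which is what lets this stage veto false
wound regions without touching true ones. The filter is monotone — it only
ever removes background, never adds it. When the cascade makes no natural
mistakes on training fixtures, hard negatives are synthesized by planting
false background components inside cellular regions; otherwise this stage
would have a single training class.

**4. Graph-cut refinement.** Patch labels are upgraded to pixel
resolution by minimizing a binary submodular energy: unary costs are
−log p with p a logistic calibration of the bilinearly upsampled
confidence; the interior of confidently labeled baseline regions (erosion
by one patch) is pinned by sentinel costs; pairwise terms are
contrast-sensitive Potts weights λ·exp(−(Iᵢ−Iⱼ)²/2σ²) on the 4-neighbor
graph, with σ² the image's mean squared neighbor difference (floored at
1e-6 for constant images). The minimum is found exactly by max-flow
(a compiled Dinic solver on the pixel grid).

### Numerical choices

* Max-flow capacities are quantized onto an integer grid with relative
  step 1e-8 of the largest capacity. Augmenting-path algorithms need not
  terminate on irrational capacities; the quantized energy differs from
  the real one by less than the number of graph edges × 1e-8 of the
  largest term, far below any decision margin we ever observed. The
  exactness property test (random energies vs exhaustive enumeration)
  holds at tolerance 1e-7.
* Seed sentinel costs are set just above the largest amount a single-pixel
  relabeling could recoup (max unary + 4λ + 1) rather than "infinity":
  extreme capacity ratios degrade max-flow performance without changing
  the optimum.
* Feature histograms use fixed bin edges, so a patch's representation does
  not depend on which image it sits in; out-of-range gradient values
  (one-sided border differences) clamp into the last bin.
* The orientation histogram of a gradient-free patch is defined as
  uniform, keeping the L1-normalization invariant intact.
* SVM hyperplanes are extracted as plain weight vectors; a model file is
  versioned JSON at full double precision and reproduces scores exactly
  after a round trip. The sign of every hyperplane is normalized at
  training time so positive always means background.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `patch_size` | 20 | px | classification unit; 10 px for the kinetics study below |
| `svm_cost` (C) | 1 | — | soft-margin cost of all linear SVMs |
| `threshold_method` | otsu | — | automatic confidence threshold |
| `connectivity` | 4 | — | patch connectivity for components |
| `lambda` | 1.0 | — | pairwise strength of the graph-cut energy |
| `logistic_scale` | 1.0 | score units | confidence-to-probability calibration |
| `seed_erosion_px` | patch size | px | margin kept free of hard seeds |
| `lbp_target_um_per_px` | 5 | µm/px | common scale of the scatter descriptor |

The defaults are fixed once and none of the analyses below re-tunes them
per image; the intent is a pipeline that runs without per-dataset
parameter fiddling.

## Wound-healing kinetics

Per frame, the wound area is the background pixel count of the final mask
(µm² via the squared pixel size). A series is truncated at the first
frame with zero background area — the operational stand-in for "analysis
until first contact between opposing borders", which avoids fitting the
post-closure plateau. Areas are normalized to the first frame, an
ordinary least-squares line is fit against time, and Pearson's r with its
two-sided t-distribution p-value (n − 2 df) quantifies linearity. A
constant series is reported as slope 0 with a degenerate flag rather than
an undefined correlation.

Treatment arms are compared by the ratio of median |slope| across wells
(median rather than mean so one failed well cannot drag the estimate;
the mean-based ratio is reported alongside) with a Wilcoxon rank sum test
on the two slope samples. The rank sum test enumerates the exact null
distribution of the observed (mid)ranks for combined sample sizes up to
12 — valid under ties — and uses a tie-corrected normal approximation
above that.

For the kinetics study we use 10-px patches instead of 20: the quantity
of interest is a boundary displacement of a few pixels per frame, and
halving the patch size halves both the detection limit for narrow wounds
and the granularity with which the confidence map tracks the moving
front. The segmentation benchmark keeps the 20-px default, which is the
appropriate unit when per-patch texture context matters most.

## Scatter-assay scoring

Each image is (1) downsampled to a common physical scale of 5 µm/px
(local-mean block reduction by the nearest integer factor, then a
bilinear adjustment to the exact target — texture statistics are only
comparable at a common scale), (2) segmented with the pipeline, and (3)
summarized by the L1-normalized histogram of rotation-invariant uniform
local binary pattern codes (P = 8 neighbors, R = 1) over all cellular
pixels. This LBP variant is the only standard one with exactly 10 code
bins: bins 0–8 are the uniform patterns with that many 1-bits, bin 9
collects non-uniform patterns. Ties resolve as neighbor ≥ center, which
makes the constant-image case deterministic (all mass in bin 8).
Diagonal neighbors are sampled on the radius-1 circle with bilinear
interpolation, so the descriptor is exactly invariant under gray-scale
shift/positive scaling and under axis-aligned rotation.

Classification is a linear SVM on the 10-bin descriptor (standardized by
default; a reduced 3-bin variant using bins {6, 7, 9} is provided).
Validation follows two protocols: leave-one-out with the default decision
threshold of zero confidence, and 100 random equal-size train/test splits
constrained to keep more than 3 minority-class images in training.

## The synthetic-data generator

No public dataset accompanies this problem, so the generator produces
calibrated images with exact truth masks emulating the features the
pipeline exploits:

* cellular regions: smoothed Gaussian noise at 2–4 px correlation length
  (amplitude `cell_texture_strength`, default 0.12 intensity units)
  modulated by a coarser bright/dark blob field — cell-scale granularity
  without modeling individual cells;
* background: smooth, with additive sensor noise (sd 0.02) and a linear
  illumination ramp (10% of the dynamic range);
* wound boundaries displaced by a sinusoid plus low-frequency noise with
  amplitude ≈ 5% of the image width, so no straight-edge shortcut exists;
* wound series close linearly in area at a configurable per-frame rate,
  with an independent texture realization per frame;
* scatter classes share the same total cellular area (35%) and differ
  only in dispersion and texture: a few large compact colonies
  (smoother, coarser texture) versus many small blobs (finer, stronger
  texture, high perimeter-to-area ratio).

Intensities are produced in [0, 1] and quantized only on file export
(8-bit PNG or 16-bit TIFF, masks as 8-bit PNG with background = 255,
plus a manifest CSV).

What the generator does **not** emulate: optical artifacts of DIC
(shear shadows, halo), debris and bubbles, uneven focus, cell-density
gradients, and boundary texture transitions (real wound edges have
partial-cell fringes). Perfect scores on synthetic fixtures therefore
demonstrate that the machinery is correct and well-calibrated — not that
real microscopy will be this clean. On real data the intended workflow is
to mark a handful of images by hand and train designated models.

## Study conditions used by the tests and the acceptance script

Problem sizes were chosen to exercise every stage at realistic geometry:

* segmentation benchmark: train on 5 wound images (200 × 200 px,
  1.24 µm/px, wound fractions 0.35–0.10 so both classifier stages see
  narrow wounds), evaluate on 20 fresh images;
* kinetics: 6-frame series at 256 × 256 px, initial wound fraction 0.3,
  closure rates {0.05, 0.1, 0.2} of the initial area per frame, 8
  replicate wells per rate; arms at rates 0.2 vs 0.1 give the
  fold-change comparison;
* scatter: 22 non-scattered + 10 scattered images at 192 × 192 px
  generated directly at the 5 µm/px descriptor scale; the segmentation
  model for this assay is trained on 4 scatter images.

## Known limitations

* The five feature sets are one reasonable instantiation of "basic
  texture features"; the extraction layer is configurable precisely
  because other choices are defensible.
* The region classifier sees only background-labeled components; a
  cellular component surrounded by wound is never re-examined.
* Graph-cut refinement inherits whatever bias the confidence calibration
  has at patch boundaries; with featureless pairwise contrast (texture
  boundaries rather than intensity edges) the boundary lands at the
  confidence zero-crossing, whose localization is limited by patch size.
* The exact rank-sum enumeration is limited to combined n ≤ 12 (beyond
  that the tie-corrected normal approximation is used), and the
  split-validation constraint assumes the minority class has at least
  `min_minority_train + 2` members.
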