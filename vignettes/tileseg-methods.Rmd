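---
title: "Whole-slide tumor segmentation from area-based annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide tumor segmentation from area-based annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Histopathological diagnosis of breast tissue rests on whole-slide images
(WSIs): gigapixel scans of H&E-stained sections. tileseg implements a
patch-based segmentation strategy for such slides built on *area-based*
annotation: experts outline only regions they consider *surely* tumor or
*surely* normal, leaving ambiguous tissue unannotated. Compared with
drawing a single tumor/normal border, this yields training data with very
little label noise — at the price that ground truth covers only part of
the slide, which shapes both training (tiles are cut strictly inside
annotated regions) and evaluation (pixel metrics are restricted to
annotated pixels).

The pipeline has four stages:

1. **Preprocessing.** White background is masked (a pixel is background
   when `min(R, G, B)` is at least a whiteness threshold), annotations are
   rasterized to per-class masks under a pixel-center even-odd rule, and
   slides can be downsampled by integer block averaging to build a
   multi-resolution database.
2. **Patch dataset.** 128 × 128 tiles are cut on a grid anchored at the
   slide origin; a tile is kept only when its entire footprint lies in one
   class mask. Classes are equalized by undersampling and slides are split
   70/10/20 into train/validation/test *by slide*, so no slide contributes
   patches to two sets.
3. **Classifier.** A compact four-layer CNN maps a tile to a tumor
   confidence in [0, 1].
4. **Segmentation.** A sliding window walks the slide at step size *s*;
   every pixel's confidence is the arithmetic mean of all windows covering
   it ((128/s)² for interior pixels), and the mean map is binarized at a
   threshold selected by an F1 sweep on the validation set.

## The classifier

The network is deliberately small: four valid convolutions with filter
counts 8, 16, 16, 32 and kernels 3×3, 3×3, 5×5, 3×3. Each convolution is
followed by per-channel batch normalization, a SELU activation (avoiding
dying-unit pathologies without extra normalization pressure), and 2×2 max
pooling. Global average pooling feeds a 2-unit softmax head; the softmax
tumor probability is the reported confidence. Training minimizes the mean
squared error between that probability and the 0/1 label with SGD
(momentum 0.75, learning rate 1e-4 by default), L2 weight decay on the
weight matrices, batch size 64, and early stopping: when the validation
loss (on a 10% stratified holdout of the training patches) has not
improved for `patience` epochs, training stops and the best-epoch weights
are restored.

Two architectural details are underdetermined by the description this
design follows, and were fixed here once: the spatial reduction between
convolutions (we use 2×2 max pooling after every block, plus global
average pooling before the head) and the L2 coefficient (default 1e-4).
With these choices the network has 12,658 parameters. The implementation
is pure R: im2col index tables turn each convolution over a whole batch
into one GEMM, so the arithmetic runs in BLAS; the backward pass
(softmax/MSE head, GAP, max-pool argmax routing, batch-norm and SELU
derivatives, col2im scatter) is derived analytically in the same layout.

Two numerical choices matter at small scale. First, batch-norm running
statistics are bias-corrected exponential averages (the raw EMA divided by
`1 - momentum^t`), so inference is unbiased even after a handful of
batches; without this, a model trained on a few hundred patches predicts
garbage in inference mode while looking fine in training mode. Second,
SELU uses the standard (λ, α) constants and LeCun-normal initialization,
the combination SELU's self-normalizing property is derived for.

### Desk-scale training schedule

The default learning rate (1e-4) and batch size (64) are calibrated for
databases of 10⁵–10⁶ patches, where an epoch performs thousands of weight
updates. The package's tests and examples run on synthetic cohorts with
~10² patches, where that schedule would perform far too few updates to
converge; they therefore pass `learningRate = 0.05`, `batchSize = 32`,
`maxEpochs = 20`, `patience = 3` through the same `classifierConfig()`
surface. This is a scale adaptation, not a change of method: the number of
gradient updates per unit of data is brought back to the regime the
defaults assume.

## Sliding-window aggregation

Anchors sit at multiples of the step; when the last multiple does not
reach the border, one extra border-flush anchor per axis guarantees every
pixel is covered (the borders of real slides are not multiples of the
step; this policy was fixed here once). Predictions are accumulated in a
sum plane and a count plane and divided once at the end — identical to
averaging all per-pixel predictions, without storing up to 256 values per
pixel. Interior pixels receive exactly (window/step)² predictions: 1, 4,
16, 64, 256 at steps 128, 64, 32, 16, 8. Binarization happens *after*
averaging, with `confidence >= threshold` mapping to tumor — a tie goes to
tumor, the conservative direction for a diagnostic aid. Pixels never
covered (impossible under the flush-anchor policy, but representable)
carry a −1 sentinel and are excluded from rendering scales and metrics.

The threshold comes from a sweep over the hundredths grid 0.00–1.00 of the
F1 score of validation-patch predictions; ties are broken toward the
*lowest* threshold, favoring sensitivity. The step size is chosen from a
time–accuracy trade-off table; wall-clock numbers in that table are
informational only and never asserted anywhere, since they are
hardware-dependent.

## The synthetic-slide generator

The clinical database this method was developed for is private, so the
package ships a generator that emulates its geometry at desk scale:
bright-field-like slides with a pure white background, rectangular tissue
regions of two classes, and annotation polygons that exactly bound the
rendered regions (integer-corner rectangles rasterize back to their own
footprint under the pixel-center, boundary-inclusive rule — a property the
tests exploit). Texture is the class signal: a cytoplasm-pink field
scattered with dark elliptic nuclei, where tumor regions are hypercellular
(default 7 nuclei per 1000 px² of radius 3–6 px, against 2 per 1000 px² of
radius 2–4 px), plus additive Gaussian color jitter (sd 6). The two
classes are assigned disjoint bands of the canvas so that no 128-pixel
window can straddle both classes — mirroring how area-based annotation
marks separated regions — while same-class regions may sit close together.

Default problem sizes were chosen once as the package's study conditions:
cohorts of 10 slides of 896 × 1280 pixels (a desk-scale stand-in for
~29,000 × 17,000 WSIs), two regions per class of 288–384 px (so the
origin-anchored tile grid always finds fully-inside tiles), 70/10/20
by-slide split, aggregation at step 32. An end-to-end run — generation,
extraction, balancing, training, sweeping, segmenting, evaluating —
completes in a few minutes on one CPU.

What the generator does *not* emulate: stain variability and stain
deconvolution structure, nuclear pleomorphism, tissue boundaries that are
not axis-aligned, scanner artifacts, or ambiguous transitional tissue.
Passing the end-to-end recovery check therefore demonstrates that the
pipeline's machinery is correct and that the classifier can learn a
texture contrast — not that the printed clinical accuracy transfers to
real slides.

## Evaluation semantics

Kernel-level (patch) metrics binarize raw confidences at the chosen
threshold; MSE is computed on the raw confidences against the 0/1 labels
and AUROC threshold-free (trapezoid over the `c >= t` operating points,
which equals the Mann–Whitney concordance). Pixel-level metrics compare
the binarized map with the rasterized annotations restricted to annotated
pixels: with area-based ground truth, an unannotated pixel is *unknown*,
not negative — the algorithm finding tumor outside the annotations may
well be correct there, and only expert review can judge it. Both pooled
and per-slide macro-averaged (mean ± sd) summaries are provided, the
latter matching the way whole-slide benchmarks are usually reported. When
precision + recall is zero, F1 is reported as 0 with a warning; AUROC on
single-class truth is NA with a warning.

## Numerical and interface decisions

- Coordinates are 0-based `(row, col)`; annotation vertices are `(x, y)`
  as GeoJSON dictates and are converted on read. Annotations are stored at
  native resolution and scaled by 1/factor when paired with a downsampled
  raster.
- Rasterization uses the even-odd rule on pixel centers with boundary
  pixels included; interior rings are holes. Deterministic and independent
  of region order; overlapping tumor/normal regions are a validation error
  naming the offending pairs.
- Downsampling averages (possibly partial) blocks and rounds half to even;
  `factor = 1` is the identity.
- The whiteness threshold defaults to 220 (8-bit); it is a free parameter
  of the background masker.
- The balancing rule is undersampling of the majority class, seeded;
  oversampling and loss weighting were considered and rejected to keep the
  training set's independence structure simple.
- Fractions in the by-slide split are honored to the nearest integer with
  the test group absorbing the remainder (10 slides → 7/1/2).
- Confidence maps persist as 32-bit TIFF (quantized at 2⁻³², far below any
  tolerance used) plus an RDS sidecar with coverage counts; masks as 0/255
  PNG; annotations as GeoJSON FeatureCollections in the QuPath dialect
  (`properties.classification.name`, case-insensitive).
- Pipeline artifacts carry an MD5 hash of the canonical YAML config;
  resuming against artifacts from a different config is refused.

## Known limitations

- The pure-R network trains comfortably at desk scale (10²–10³ patches)
  but is not intended for 10⁵-patch clinical databases; the architecture
  and training rules transfer unchanged to a GPU framework.
- `FunctionClassifier` mocks and the constant-model invariances verify the
  aggregation machinery, but no synthetic fixture can certify clinical
  performance (see the generator's non-goals above).
- Pyramidal WSI containers (SVS/NDPI) are out of scope; inputs are flat
  PNG/TIFF rasters, assumed already exported at the working resolution.
- Stain normalization is not implemented; the generator's color model
  makes it unnecessary for the shipped tests.
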