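---
title: "Whole-slide segmentation and analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide segmentation and analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`wsikit` implements a patch-based pipeline for segmenting gigapixel
whole-slide images (WSI) and for the pathology analyses that consume the
resulting tumor-probability heatmaps. This vignette is the package's own
account of the underlying models, the tunable parameters and their
defaults, the numerical choices made where the method description leaves
room, and what the synthetic test bed does and does not demonstrate.

## The pipeline model

A WSI is modelled as a `pyramid_image`: an ordered list of RGB rasters
with level 0 the full-resolution scan, per-level downsample factors
(strictly increasing, factor 1 at level 0), and the physical resolution
`mpp0` in microns per pixel at level 0. Coordinates are 0-based with `x`
as column; regions are addressed by their *center* at level 0, because
the inference sampling grid is a lattice of centers. Out-of-bounds reads
are filled with white: padding must look like glass, so that it can never
masquerade as tissue.

The stages compose as: tissue mask → patch sampling → per-patch
prediction (ensemble-averaged) → overlap-averaged stitching → heatmap →
{staging features, burden, uncertainty}.

### Tissue masking

Tissue is separated from glass on a low-resolution level by Otsu
thresholding of the HSV *saturation* channel: stained tissue is
chromatic, glass is nearly achromatic, so the saturation histogram is
bimodal. Otsu runs on a fixed 256-bin (8-bit) histogram, which makes the
threshold deterministic and independent of image size. Two numerical
guards apply:

* a saturation range below `sat_epsilon` (default 1e-3, e.g. a pure-glass
  raster) is a degenerate histogram — the mask is empty and flagged,
  rather than thresholded at noise;
* the binary cleanup is closing then opening with disc structuring
  elements (default radius 2 at the mask level). The operation pair is
  named by the method; the radii are not, so they are exposed in
  `mask_params()`. The closing-then-opening composition is idempotent,
  which the tests exercise.

Slides whose background contains black scanner regions break the
saturation histogram; `preprocess_camelyon()` replaces pixels with all
three channels below `black_threshold` (default 10/255 — "black" is not
defined more precisely by the method, so it is a parameter) with white
and then applies a 7×7 median blur to the whole image.

The *mask level* defaults to the pyramid level whose longer side is
nearest 2,000 px: large enough that small tissue fragments survive,
small enough that masking is essentially free. It is configurable
because real scanners differ in pyramid depth.

### Patch sampling and augmentation

Training patches (default 256 px) are extracted at level 0. A patch is
labelled *tumor* iff its footprint contains at least one tumor pixel,
and classes are balanced exactly (`n_per_class` each). Eligible tumor
centers are pre-screened with a tumor mask dilated by half the patch
size at the mask level — a superset of the truth — and every sampled
candidate is then verified against the exact level-0 footprint, so the
screening is an optimization, not an approximation; the equivalence is a
unit test. If a class has no eligible centers the sampler returns fewer
with a warning instead of silently duplicating coordinates.

Center perturbation draws an offset uniformly over a disk of radius 128
px (so the expected offset magnitude is 2r/3 ≈ 85 px), rounded to
integer pixels without ever exceeding the radius. Color augmentation
shifts brightness, contrast, hue and saturation by draws uniform within
±(64/255, 0.75, 0.25, 0.04) respectively; these maxima are taken as
*fractional* units on the [0, 1] scale (the hue delta wraps modulo 1),
which is the interpretation consistent with 64/255 being a fraction.
Geometric transforms apply identically to patch and mask; color
transforms to the patch only. Normalization is a separate, bundled step:
per-channel `(x − mean)/sd` with constants stored in the model bundle,
so a trained model always normalizes the way it was trained.

The inference grid (default patch 1024 px, stride 512 px) keeps a
lattice center iff its mask-level pixel is tissue. The 50 % overlap is
the stated accuracy/cost balance; stitching averages predictions at
overlaps, which removes the blockish seams of non-overlapping tiling.
The lattice starts at `floor(patch_size/2)` so every footprint lies
within the slide.

### Loss

The hybrid loss is `α·CL + β·DL_BG + γ·DL_FG` with defaults α = 0.5,
β = γ = 0.25 (cross-entropy and Dice weighted equally). Numerical
choices:

* the printed form of the cross-entropy term in the source method lacks
  the conventional negation and reduction; it is implemented as the
  *negated mean* over pixels, `−(1/N) Σ [g log p + (1−g) log(1−p)]`, so
  that minimizing the loss means fitting the data. Probabilities are
  clipped to [1e-7, 1 − 1e-7];
* the Dice loss carries a smoothing ε = 1e-6 in numerator and
  denominator, so an empty prediction against an empty truth scores 0
  rather than 0/0.

The analytic gradient of the full hybrid loss is implemented alongside
and verified against finite differences.

### Predictors, ensembling, training

Everything downstream of patch extraction depends only on the
`predict_patch()` contract: RGB patch in, probability map of identical
spatial dimensions out, deterministic in inference mode. The ensemble
prediction is the pixel-wise arithmetic mean of member posteriors.
Full-scale pretrained encoder–decoder backbones are deliberately out of
scope here; the package ships

* `mini_fcn()`: a small trainable FCN (three 3×3 conv + ReLU blocks and
  a 1×1 sigmoid head, He initialization, Rcpp/Armadillo im2col
  convolutions) whose first two blocks form the "encoder" parameter
  group;
* deterministic mocks: `constant_predictor()`, `oracle_predictor()`
  (returns the ground-truth crop, optionally with seeded noise), and
  `pixel_predictor()` (a pointwise color rule, exactly equivariant under
  flips/rotations — useful for uncertainty tests).

The training contract (`train_segmentation_model()`) is ADAM with
per-patch updates on the hybrid loss; a stepwise deterministic
learning-rate decay (pipeline default 1e-4 halved every 4 epochs — the
method names only "decayed every few epochs", so the schedule is
configuration); encoder freezing for the first two epochs *when the
model declares a pretrained encoder* (the mini-FCN does not, so its
tests train all layers from epoch 1 with a from-scratch rate of 3e-3);
and early stopping at the first validation-loss increase (patience 1 by
default), returning the best-validation weights. Ensemble members are
meant to be trained on distinct cross-validation folds derived from one
seed.

### Stitching and heatmap materialization

Patch maps are accumulated into level-0 sum and coverage-count grids;
the heatmap value at a pixel is sum/count where count > 0 and 0
elsewhere, which is exactly the mean of all patch predictions covering
the pixel — the tests compare against a brute-force per-pixel oracle at
1e-12. Reduced-level heatmaps block-reduce the *sum and count grids
first* and divide afterwards, so downscaling and overlap averaging
commute. At desk scale the level-0 accumulators fit comfortably in
memory; for genuinely gigapixel slides the same arithmetic applies
per-tile.

### Uncertainty

Aleatoric uncertainty per patch is the per-pixel *population* variance
(the expectation form of the estimator, hence /n, not /(n−1)) of
predictions across test-time augmentations, each output mapped back
through the exact inverse transform. The TTA set defaults to identity
plus the three right-angle rotations plus both flips: the method names
{rotation, flips} without stating angles or identity inclusion, so the
set is configuration; including identity makes the estimator's mean the
ordinary prediction. Epistemic uncertainty is the population variance
across ensemble members. Aleatoric maps are computed per model and
averaged across members by default (a per-member flag exists). Since
outputs live in [0, 1], variances are bounded by 0.25.

### Staging

Heatmaps are binarized at p = 0.5 and p = 0.9 (strict `>`), components
are 8-connected, and the fixed 32-feature vector is assembled: largest
region's major axis at both thresholds; largest area at 0.5; tumor/
tissue area ratio; supra-threshold pixel count; {maximum, mean,
variance, skewness, kurtosis} of per-region area, perimeter,
eccentricity, extent, solidity (25 features); mean of regions' mean
confidence; and region count — the last 28 at p = 0.9. Conventions:
crack perimeter (count of exposed pixel edges); moment-based major axis
`4·sqrt(λ₁)` and eccentricity `sqrt(1 − λ₂/λ₁)`; solidity uses a
rasterized convex hull. Lengths stay in *pixels at the heatmap level*
with the microns-per-pixel carried as an attribute — only the size
*rules* convert to millimetres (`major_axis × mpp / 1000`), so the
features themselves are resolution-honest. An empty heatmap maps to the
all-zero vector; with fewer than two regions the dispersion statistics
are defined as 0.

Typing follows the size bands: 0 → negative; ≤ 0.2 mm or < 200 cells →
ITC; ≤ 2 mm → micro; > 2 mm → macro (cell count is an optional input,
never estimated from pixels). The patient stage: only negatives → pN0;
only ITCs → pN0(i+); micro but no macro → pN1mi; macro present with 1–3
involved nodes → pN1, with ≥ 4 → pN2. Two rules the stage table leaves
open are fixed here: ITC-only nodes do not count toward the pN1/pN2
node tally (otherwise pN0(i+) could not exist), and patients with more
than 9 involved nodes clamp to pN2 (unreachable with ≤ 5 nodes per
patient).

The classifier is an ensemble of four Random Forests; the four member
variants are not specified beyond "different subsets", so they are
implemented as 2 stratified subsamples × {raw, SMOTE+Tomek-balanced}
training data. SMOTE oversamples each minority class to parity by
interpolating between a sample and one of its k = 5 nearest same-class
neighbours; Tomek links (mutual nearest-neighbour pairs from opposite
classes) are then removed, both ends. A minority class of size 1 is an
error (SMOTE needs a neighbour). Votes are combined by majority with
ties broken toward the *higher* metastasis category — the
clinically conservative direction.

### Tumour burden

The six-step burden algorithm: threshold the viable-tumor heatmap
(default 0.5); remove objects smaller than `min_object_px` and fill
holes smaller than `max_hole_px` (defaults 0.05 % and 0.01 % of the
tissue area — the operations are named by the method, the sizes are
not); take *one* convex hull over all viable pixels (each sample
carries a single whole-tumor region); intersect with the tissue mask;
report viable/whole area ratio, 0 when whole is empty. The hull is
rasterized by a vectorized half-plane test over `chull()` vertices
(inclusive of the boundary); `mgcv::in.out` serves as an independent
oracle in the tests. Because numerator and denominator rescale
together, the burden is stable across heatmap levels to within
discretization error.

## The synthetic slide generator

`generate_slide()` emulates the gross structure the pipeline actually
keys on: a white glass background (0.955–1.0), elliptical tissue blobs
in an H&E-like pink (RGB ≈ 0.87/0.58/0.77, saturation ≈ 0.33 — safely
above the achromatic background, since the masking thresholds
saturation), darker purple tumor ellipses strictly inside tissue,
per-pixel Gaussian texture noise (sd 0.02), per-blob stain jitter,
an optional near-black border band (the scanner artifact), and a
≥ 3-level pyramid with factor-4 steps built by block-mean reduction.
Ground truth comprises the tissue mask, the viable-tumor mask, and a
whole-tumor mask defined as the convex envelope of the tumor nests
clipped to tissue. All randomness flows from the single spec seed
through a private RNG stream (the caller's RNG state is untouched), so
identical specs are bit-identical.

`generate_patient()` plants one slide per lymph node with the largest
lesion's physical major axis sampled inside the size band of its
planned label. Two generator choices matter here: patient slides use
`mpp0 = 8` µm/px so that millimetre-scale rules fit on a 1024² raster
(a 1024 px slide spans 8.2 mm), and sizes are sampled with a margin
away from the 0.2 mm and 2 mm boundaries (ITC 0.08–0.16 mm, micro
0.4–1.6 mm, macro 2.4–3.6 mm) so that recovery tests measure the
pipeline, not pixel-rounding luck at a band edge.

What the generator does *not* emulate: nuclei-level texture, stain
deconvolution physics, pen marks and coverslip artifacts, tissue folds,
scanner focus variation, and the full size range of clinical lesions.
Consequently, passing tests demonstrate that the *plumbing* is correct —
geometry, balancing, losses, averaging, rules — and that the training
loop can fit a color-separable target; they do not certify segmentation
accuracy on real H&E tissue, which depends on the backbone and training
data.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
default slides 512², training slides 1024², patient slides 1024² at
8 µm/px, inference patches 64–256 px with 50 % overlap, mini-FCN
training on 100–200 patches of 256² for up to 6 epochs, Random-Forest
experiments on 48 synthetic feature vectors. These sizes keep a full
run in the minutes range on one CPU while leaving every code path —
including pyramid IO, dilation screening, stitching and staging —
exercised at realistic aspect ratios.

## Known limitations

* The shipped mini-FCN is a correctness vehicle, not a competitive
  backbone; leaderboard-scale results require pretrained encoders and
  GPU training, both out of scope.
* The whole-tumor convex-hull approximation under-covers genuinely
  non-convex whole-tumor regions and over-covers widely separated
  nests with little intervening tumor.
* `estimate_whole_tumor` assumes one whole-tumor region per sample; a
  multi-lesion sample would need per-lesion hulls.
* The staging Random Forests are only as good as the heatmap features;
  with few training patients the SMOTE interpolation can manufacture
  borderline feature vectors near band edges.
* CRF post-processing, multi-resolution FCNs and artifact classifiers
  are not implemented.
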