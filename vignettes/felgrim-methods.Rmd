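---
title: "Methods: automated Feline Grimace Scale scoring from facial landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated Feline Grimace Scale scoring from facial landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felgrim)
```

## The problem

The Feline Grimace Scale (FGS) assesses acute pain in cats from five
facial action units (AUs): ear position, orbital tightening, muzzle
tension, whiskers change and head position. Each AU is scored 0, 1 or 2;
the total FGS score is the sum of scored AUs divided by the maximum
possible score (2 per scored AU), giving a ratio in [0, 1]. Scores at or
above the published intervention cut-off of 0.39/1 indicate a cat likely
in pain; when building model labels a cut-off of 0.4/1 is used instead,
and both values are retained verbatim — the binarization threshold is
therefore always an explicit argument, never a hidden constant.

felgrim implements the two-phase automation of this scale:

* **Phase I** concerns locating 37 facial landmarks on an image:
  alignment and edge-filter preprocessing, the training-time
  augmentation recipe, NRMSE-family evaluation of landmark predictors,
  and a small reference convolutional network.
* **Phase II** turns the 37 landmarks into 35 similarity-invariant
  geometric descriptors and predicts FGS scores with gradient-boosted
  trees under several multi-rater aggregation rules.

Because no clinical image dataset ships with the package, a synthetic
cat-face generator provides landmark configurations, rendered raster
faces and imperfect raters with the statistical structure the pipeline
assumes; every stage is exercised end to end on generated data.

## The landmark schema

Thirty-seven landmarks are defined, indexed 1..37 (1-based in files and
APIs), with pixel coordinates (origin top-left, y downward). Four role
sets are fixed by the scale's methodology:

* rotation set {13, 14, 17, 18} — the orbital landmarks whose two
  eye-group centroids define the face rotation angle;
* crop set {3, 10, 29, 30, 31, 32, 36, 37} — peripheral landmarks whose
  bounding box drives face cropping;
* normalization pair (33, 34) — the nose-wing landmarks whose distance
  normalizes landmark prediction errors;
* NRMSEw exclusion set {6, 7, 27, 28, 29, 30, 31, 32, 36, 37} — the ten
  landmarks dropped in the weighted error variant (27 remain).

The exact anatomical allocation of every index to an AU is not fully
recoverable from the published material, so the package ships one
canonical allocation chosen to satisfy every stated constraint (the
rotation set must be orbital, the crop set peripheral, the pair 33/34 on
the muzzle): ears 1–8, head 9, 10, 35–37, whiskers 11, 12, 27–32,
orbital 13–20, muzzle 21–26, 33, 34 (8/8/8/8/5 landmarks per AU). Any
schema satisfying the structural invariants of `fgs_schema()` is
accepted by all downstream functions, so the true supplementary
definitions can be dropped in without code changes.

Annotation files round-trip in two dialects: the annotation tool's
plain-text format (one `index x y` line per landmark, full `%.17g`
precision, bit-identical round trips) and a wide CSV
(`image_id, l1_x, l1_y, ..., l37_y`).

## Geometric descriptors

Thirty-five descriptors summarize facial configuration: angles (degrees,
unsigned), ratios of inter-landmark distances, and ratios of
quadrilateral areas (shoelace formula), most averaged over left/right
homologous parts; 10/5/8/5/7 descriptors belong to ear position, orbital
tightening, muzzle tension, whiskers change and head position
respectively. Every descriptor is invariant under translation, rotation,
uniform scaling and reflection of the landmark configuration (verified
to 1e-9 over random similarity transforms in the test suite), so the
features capture expression, not pose or face size — the property that
motivates using ratios and angles in the first place.

As with the AU allocation, the exact landmark sets of the 35 published
descriptors are not recoverable from the main text. The default registry
is therefore authored in-package to match every stated constraint
(counts per AU; distance ratios dominating the ear/whisker/muzzle
families, angles the orbital family; left/right averaging), with
denominators anchored on the pose-stable nose-wing span (33–34) or a
quadrilateral over the medial canthi and nose wings. Alternative
registries load from a declarative YAML file (`read_registry()`);
`subset_registry()` implements the feature-family exclusions used in
model comparisons (dropping whiskers change leaves 30 descriptors, head
position 28, both 23).

## Scoring and multi-rater aggregation

`total_fgs()` implements the scale's ratio with missing-AU handling (a
missing AU removes 2 from the denominator). Rater disagreement is
resolved by aggregation rules applied per image: AND/OR over binarized
labels (AND = every rater calls the image painful), mean/maximum/minimum
over total ratios, and mode/maximum/minimum over per-AU ordinal scores.
Mode ties are broken to the *lowest* tied score by default — a
deterministic, clinically conservative choice (a tie never escalates the
severity); `tie = "highest"` is available. The laws relating these rules
(min ≤ mean ≤ max, AND ≤ OR, aggregation of identical values is the
identity) are checked exhaustively over all rater multisets of size ≤ 4.

## Prediction models

Three tasks are supported on descriptor features, all via gradient
boosting (xgboost backend):

* **binary** — painful vs non-painful at an explicit cut-off; class
  imbalance is handled by `scale_pos_weight`, the negative/positive
  count ratio, recomputed on each training fold;
* **regression** — the total FGS ratio, squared-error objective;
* **ordinal** — one AU's 0/1/2 score, fit as a 3-class softmax model
  with MSE between predicted and true class integers reported, matching
  how ordinal errors are conventionally summarized for this scale. A
  cumulative-link formulation would also be defensible; the softmax
  choice keeps one boosting backend across all tasks and is the
  documented default.

Hyperparameters are tuned by exhaustive grid search with shuffled 5-fold
cross-validation (accuracy for binary, negative MSE otherwise), refit on
all data at the best combination. The published study does not print its
candidate grid; the shipped default covers trees {100, 300}, learning
rate {0.05, 0.1, 0.3}, L1 weight {0, 0.5, 1}, depth {3, 5} and row and
column subsampling {0.8, 1.0}, and is fully configurable. Folds are
shuffled with the caller's seed, stratified automatically if a shuffled
split would leave a training fold single-class; all fits run
single-threaded with a fixed boosting seed, so results are exactly
reproducible.

Two feature-selection procedures mirror the study's:

* **RFE** — greedy backward elimination, dropping the lowest
  gain-importance feature per step; each subset size is scored by
  4-fold shuffled CV and the best-scoring (smallest on ties) subset is
  returned.
* **Boruta–Shapley** — each trial appends a shuffled shadow copy of
  every feature, fits the model, computes per-feature mean absolute
  Shapley attributions (exact TreeSHAP from the boosting backend),
  z-scores them within the trial, and records a hit when a real feature
  exceeds the maximum shadow z-score; features with hit counts
  significantly above chance under a one-sided binomial test
  (p0 = 0.5, alpha = 0.05) are relevant. With the default 20 trials a
  feature needs 15 hits.

`pca_project()` standardizes features and projects onto principal axes
for the painful/non-painful separation plots (`autoplot()`).

## Landmark-error metrics

The landmark prediction error is, despite its conventional name, a mean
normalized Euclidean distance: the average over images and landmarks of
the prediction-to-truth distance divided by the image's ground-truth
nose-wing distance, times 100. It is implemented exactly in that printed
form (no root of a mean of squares) and checked against an independent
double-loop oracle. NRMSEw restricts to the 27 retained landmarks;
per-AU errors restrict to one AU's landmark set and recombine to the
overall value as a landmark-count-weighted mean. Normalization uses the
coordinate frame in which predictions are evaluated; since the error is
invariant under a joint similarity transform of predictions and truths,
the choice of frame is immaterial up to that equivalence.

## The reference landmark network

No deep-learning runtime is assumed: the reference network is
implemented natively (im2col convolutions, Adam, MSE on coordinates
normalized by the template frame). The trunk is three 3x3 stride-2
convolution blocks (8/16/32 filters, ReLU, 'same' padding) — small
enough for CPU training; pretrained mobile backbones are deliberately
out of scope and pluggable behind the same `model_report()` interface.
The configurable top structure reproduces the architecture variants
compared in the study: global-average-pooling vs flatten head, up to two
dense layers, and an optional block of parallel convolutions with
symmetric (3x3), asymmetric (1x3 + 3x1) or hybrid kernels; the output is
always a 74-wide linear layer (37 x/y pairs).

Training defaults: Adam at 3e-3 (chosen so the small trunk converges
within a few dozen epochs at the package's problem sizes), batch 32,
20% validation split, early stopping with patience 5 and best-weight
restore. Everything is seeded and single-threaded, so training histories
are bit-reproducible. The package's training-scale sanity check — 500
rendered 64x64 synthetic faces, 30 epochs — requires the net to beat
the constant-landmark baseline (predicting the mean training
configuration everywhere), which it does with a wide margin (roughly
27% vs 39% NRMSE); absolute values on synthetic renders are not
comparable to photographic benchmarks and are not meant to be.

## The synthetic generator

The generator is the package's study population, not a test dial; its
defaults are fixed once and all performance checks inherit them.

* **Template and deformations.** A canonical 37-landmark face on a
  256-px frame (nose-wing distance 36 px). Each AU has a displacement
  field, linear in its latent intensity in [0, 1], moving landmarks the
  way painful cats present: ears lower and rotate outward, eye apertures
  narrow, the mouth compresses, whiskers straighten and advance, the
  head outline lowers relative to the eyes.
* **Nuisance variation.** Isotropic Gaussian landmark noise
  (sigma = 1.5 px, about 4% of the normalization distance), then a
  random similarity transform: rotation ±15°, scale 0.9–1.15,
  translation ±10 px.
* **Population.** Painful faces (prevalence 0.5 by default) draw AU
  intensities from TruncNorm(0.8, 0.15) on [0, 1]; non-painful from
  TruncNorm(0.1, 0.1) — separable but overlapping groups (the primary
  descriptor of every AU separates them at Cohen's d > 0.8 under
  default noise).
* **Raters.** The true AU level discretizes the intensity at 1/3 and
  2/3. Each rater scores each AU independently from a row-stochastic
  error matrix; the default gives 0.8 to the correct level, 0.15/0.05 to
  the adjacent/two-off levels (level 1, which has no two-off neighbour,
  uses 0.1/0.8/0.1).
* **Rendering.** A deterministic rasterization (filled head-and-ears
  outline, eye and muzzle polygons, whisker polylines) for the Phase-I
  image path.

What the generator does **not** emulate: coat color and texture,
lighting, occlusion, breed morphology, non-frontal pose, or correlated
rater bias. Passing the synthetic-analog performance checks therefore
demonstrates that the pipeline's machinery is correct and recovers a
signal of the assumed structure at realistic noise levels — not that
the same numbers would be achieved on clinical photographs.

## Numerical choices and degenerate inputs

* Coordinates are continuous pixels; the pixel at matrix index (i, j)
  has its center at (j − 0.5, i − 0.5), so raster warps and landmark
  transforms agree to sub-pixel tolerance.
* Rotation angles use the screen convention (counterclockwise as
  displayed positive, y down); alignment rotates about the image
  center.
* The aligned-face crop box (crop-set bounding box + 10% margin per
  side, output 224x224 by default) grows as needed to contain all 37
  landmarks — keeping every landmark visible outranks face size or
  position.
* 3x3 filter kernels use reflect padding; the Laplacian is the
  4-neighbor kernel; Prewitt/Sobel responses combine as
  0.5|vertical| + 0.5|horizontal| (the combination weights are not
  printed in the source methodology; equal weights are the natural
  symmetric choice). The bilateral pre-filter uses diameter 3 and
  sigmas of 100 on the 0–255 intensity scale.
* Augmentation parameters draw uniformly within their printed ranges;
  the two rotation sub-ranges are chosen with probability 1/2 each, and
  a flip (left-right, rotate −90 or rotate −270) is applied with
  probability 1/2. The face-crop acceptance rule is strict: a crop of
  exactly 0.4 of the original area is rejected.
* Degenerate geometry (coincident angle arms, zero ratio denominators,
  zero normalization distance, collapsed crop boxes) raises classed
  errors naming the offending descriptor or image; annotation
  validation reports rather than errors.
* Mode ties go to the lowest score; CV ties in RFE go to the smaller
  subset; both deterministic.

## Problem sizes used by the checks

The package's own verification runs at desk scale, chosen to keep the
full suite fast while leaving the statistical conclusions unambiguous:
the synthetic-analog model checks use 1200 faces (1000 train / 200
held out, the same split sizes as the published Phase-II protocol's
test set of randomly selected images, scaled to the generator);
feature-selection recovery uses 400–600 samples with 10–20 planted
features; the landmark-network check uses 500 training renders at
64x64 for 30 epochs. `scripts/acceptance.R` re-runs the model checks
from scratch with the package-default hyperparameter grid.

## Known limitations

* The default AU allocation and descriptor landmark sets are canonical
  stand-ins consistent with all published constraints, not the
  unpublished supplementary definitions.
* Ordinal models are softmax classifiers scored by class-integer MSE;
  they ignore the ordering during fitting.
* The reference network is a deliberately small CPU model; it
  demonstrates the training/evaluation contract, not state-of-the-art
  landmark accuracy.
* Synthetic-analog performance bounds transfer to real data only to the
  extent the generator's assumptions (linear deformations, isotropic
  noise, independent raters) hold.
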