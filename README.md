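# felgrim

Automated **Feline Grimace Scale (FGS)** scoring from facial landmarks,
for veterinary researchers and engineers building acute-pain assessment
tools for cats.

The FGS scores five facial action units (AUs) — ear position, orbital
tightening, muzzle tension, whiskers change, head position — each as
0, 1 or 2. The total score is

```
FGS = (sum of scored AU values) / (2 x number of scored AUs)  in [0, 1]
```

with scores >= 0.39/1 indicating a cat likely in pain (0.4/1 when
building model labels). felgrim implements the full automation pipeline
around this scale:

* **Schema** — the 37-landmark / 5-AU facial schema with its special
  role sets (rotation landmarks 13/14/17/18, crop landmarks
  3/10/29–32/36/37, normalization pair 33–34, NRMSEw exclusion set),
  plus annotation file I/O (`txt` and CSV dialects) and validation.
* **Preprocessing** — face alignment from the orbital landmarks,
  Laplacian/bilateral/Prewitt/Sobel edge filters, the randomized
  augmentation recipe (rotation, shear, flips, photometric transforms,
  Gaussian blur), and the strict 0.4-area face-crop acceptance rule.
* **Descriptors** — 35 similarity-invariant geometric descriptors
  (angles, distance ratios, area ratios; 10/5/8/5/7 per AU), evaluated
  to a tidy feature table.
* **Scoring** — FGS totals with missing-AU handling, pain binarization,
  and all multi-rater aggregation rules (AND/OR, mean/max/min,
  mode/max/min with a deterministic lowest-tie rule).
* **Models** — gradient-boosted trees (xgboost backend) for binary,
  regression and ordinal tasks with shuffled 5-fold CV grid search,
  `scale_pos_weight` class weighting, RFE and Boruta–Shapley feature
  selection (exact TreeSHAP), AUROC/MSE metrics and standardized PCA.
* **Landmark evaluation** — the NRMSE family (overall, NRMSEw over the
  27 retained landmarks, per-AU), and a small natively implemented
  reference CNN (GAP/flatten heads, parallel
  symmetric/asymmetric/hybrid convolution blocks, 74-wide output).
* **Synthetic generator** — a 37-landmark cat-face template with
  per-AU pain deformations, landmark noise, pose nuisance, raster
  rendering and imperfect simulated raters, so the whole pipeline is
  testable without clinical data.

## Worked example

```r
library(felgrim)
library(dplyr)

# 1. simulate a study population: 300 faces, 3 raters each
ds <- generate_dataset(300, generator_params(prevalence = 0.5), seed = 1)
ds
#> <fgs_dataset> 300 faces (160 painful), 900 rater rows, seed 1

# 2. landmark annotations -> 35 geometric descriptors per face
features <- compute_features(ds$annotations)
dim(features)
#> [1] 300  36     # image_id + 35 descriptor columns

# 3. rater scores -> AND-aggregated pain labels at the 0.4 cut-off
labels <- ds$raters |>
  score_raters(threshold = 0.4) |>
  aggregate_raters("binary", "AND")

# 4. grid-searched binary classifier, held-out evaluation
df <- left_join(features, labels, by = "image_id")
split <- train_test_split(nrow(df), test_n = 60, seed = 1)
fit <- grid_search_cv(df[split$train, 1:36], df$label[split$train],
                      task_spec("binary", aggregation = "AND"),
                      seed = 1)
evaluate_model(fit, df[split$test, 1:36], df$label[split$test])
#> # A tibble: 1 x 5
#>   task       n accuracy auroc   mse
#>   <chr>  <int>    <dbl> <dbl> <dbl>
#> 1 binary    60        1     1    NA
```

The held-out accuracy and AUROC of 1 on all 60 test faces say the
boosted model recovers the pain state from geometry alone on this small
synthetic population (larger runs land near 99% accuracy / 0.99 AUROC);
`glance(fit)` shows the winning hyperparameters and the
fold-level CV table is in `tidy(fit)`. The same feature table drives
regression on mean-aggregated total scores, per-AU ordinal models,
`rfe_select()` / `boruta_shap_select()`, and `pca_project()` +
`autoplot()` for the painful/non-painful separation plot.
`run_phase2()` runs the whole task x aggregation x feature-subset grid
in one call.

A thin command-line veneer ships in `inst/cli/felgrim.R`
(`schema show`, `annot validate`, `simulate`, `features`, `score`,
`nrmse`).

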