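# randnet

Ensemble classification of human embryonic stem-cell (hESC) images with an
autoencoded feature extractor.

Phase-contrast video of hESC cultures produces thousands of cropped
single-object images, of which only a small fraction can be expert-labeled
into the six morphological classes relevant to toxicology assays: cell
cluster, debris, unattached cell, attached cell, dynamically blebbing
cell, apoptotically blebbing cell.  **RandNet** leverages the unlabeled
majority: a convolutional autoencoder is pretrained on unlabeled crops
with the summed pixel-wise binary cross-entropy

$$L_{AE} = -\sum_i \sum_r \sum_c I^{(i)}(r,c)\log K^{(i)}(r,c) + (1-I^{(i)}(r,c))\log(1-K^{(i)}(r,c)),$$

its encoder is cloned into *n* subnetworks fine-tuned (summed categorical
cross-entropy, Adam) on independent *stratified bootstrap* resamples of
the labeled pool, and a small stacking network fuses the *n* probability
vectors into the final decision.  Bagging plus stacking reduces variance
and overfitting relative to a single network.  Performance is read off a
confusion matrix with true classes in columns: overall accuracy
$ACR = \frac{1}{N}\sum_i CM_{ii}$ and per-class recall
$TPR_j = CM_{jj}/N_j$.

The package provides, for R users working on microscopy image
classification:

* the full training pipeline (`train_randnet()`,
  `select_num_subnetworks()`, `final_fit_and_holdout()`) with its own
  conv/pool/dense engine (Rcpp/RcppArmadillo) — autoencoder, subnetworks,
  stacking head, Adadelta and Adam;
* the data pipeline: bicubic normalize/resize, stratified 75/25 split,
  stratified k-fold, stratified bootstrap (`normalize_and_resize()`,
  `stratified_split()`, `stratified_kfold()`, `stratified_bootstrap()`);
* confusion-matrix evaluation in exact rational arithmetic
  (`confusion_matrix()`, `metrics_report()`, `read_confusion_matrix()`);
* a seeded synthetic generator of the six classes standing in for the
  unreleased video dataset (`generate_class_image()`,
  `generate_dataset()`);
* a command-line wrapper (`inst/scripts/randnet`) over `run_command()`
  with `simulate | pretrain | train | select | evaluate | end-to-end`.

## Worked example

The published out-of-sample confusion matrix ships as a plain-text
fixture.  Reading it and asking for the metrics report:

```r
library(randnet)
cm <- read_confusion_matrix(system.file("extdata",
        "cm_randnet_hesc_test.txt", package = "randnet"))
metrics_report(cm)
#> overall accuracy: 96.28%  (n = 888)
#>   cell_cluster         96.86%
#>   debris               96.89%
#>   unattached_cell      93.80%
#>   attached_cell        98.30%
#>   dynamic_blebbing     94.17%
#>   apoptotic_blebbing   96.09%
```

The 96.28 % is 855/888 — the trace over the total — and each recall is the
diagonal entry over its true-class column total (e.g. attached cell:
173/176 = 98.30 %), printed at two decimals, half-up.

Training end to end on synthetic data (desk scale — 64×64 crops, 5
subnetworks, ~2 minutes on one CPU):

```r
ds  <- generate_dataset(synthetic_config())   # 6x60 labeled + 600 unlabeled
fit <- final_fit_and_holdout(ds$labeled, ds$unlabeled,
                             config = desk_config(), seed = 1)
fit$metrics$acr          # held-out accuracy on the untouched 25% split
#> [1] 1
fit$model$stacker$input_dim
#> [1] 30                 # 5 subnetworks x 6 classes
```

`fit$confusion` holds the 90-sample test confusion matrix (15 per class:
floor(0.25 × 60)); `fit$model$provenance$stages` records the executed
pipeline order (normalize → pretrain → extract encoder → bootstrap →
fine-tune → stack → train stacking head → final model).

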