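---
title: "RandNet: bagged convolutional subnetworks with an autoencoded feature extractor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RandNet: bagged convolutional subnetworks with an autoencoded feature extractor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Phase-contrast video of human embryonic stem cell (hESC) cultures yields
large numbers of cropped single-object images — "detected components" — of
which only a small fraction can be labeled by experts.  Each crop belongs
to one of six morphological classes: cell cluster, debris, unattached
cell, attached cell, dynamically blebbing cell, apoptotically blebbing
cell.  Annotating assays by hand is slow and error-prone, so the goal is a
classifier that exploits the abundant *unlabeled* crops as well as the
scarce labeled ones.

RandNet does this with three ingredients:

1. **Unsupervised pretraining.**  A convolutional autoencoder is trained
   on the unlabeled pool with the summed pixel-wise binary cross-entropy
   $$L_{AE} = -\sum_{i=1}^{N_S}\sum_{r=1}^{N_R}\sum_{c=1}^{N_C}
     I^{(i)}(r,c)\log K^{(i)}(r,c) + (1-I^{(i)}(r,c))\log(1-K^{(i)}(r,c)),$$
   where $I$ is the normalized input image and $K$ the sigmoid
   reconstruction, optimized with Adadelta.  The encoder half becomes a
   generic feature extractor.
2. **Bagging.**  The encoder is cloned into $n$ subnetworks, each topped
   with a small classification head ("topper") and fine-tuned — encoder
   weights unfrozen — on its own *stratified bootstrap* resample of the
   labeled training pool, using the summed categorical cross-entropy
   $$L_{CCE} = -\sum_{i=1}^{N_S}\sum_{j=1}^{M} y_{ij}\log p_{ij}$$
   with Adam.  Because fine-tuning moves the encoder weights, distinct
   resamples produce genuinely diverse ensemble members.
3. **Stacking.**  The $n$ class-probability vectors are concatenated into
   an $n \times 6$-dimensional input to a deliberately simple stacking
   network (two main dense layers, softmax output) which is trained on the
   full training partition with the subnetworks frozen and makes the final
   decision.  A `joint_finetune` config flag optionally adds a joint pass
   that backpropagates the stacking loss into all subnetworks; the default
   keeps the subnetworks frozen, which preserves the diversity created by
   the bootstrap stage — the usual stacked-generalization practice.

Evaluation uses the confusion matrix with **columns indexing the true
class** and rows the predicted class.  The overall accuracy (average
classification rate) is $ACR = \tfrac{1}{N}\sum_i CM_{ii}$ and the
per-class recall is $TPR_j = CM_{jj}/N_j$ with $N_j$ the column-$j$ total.
Both are exact rationals of the counts; rounding (two decimals, half-up)
happens only at presentation.

## Default parameters

`randnet_config()` encodes the full-scale configuration: input crops
resized to 224×224 by bicubic interpolation then divided by 255 (resize on
raw values first; the bicubic kernel is Keys $a=-0.5$ without
anti-aliasing, clamped after interpolation because cubic kernels
overshoot); autoencoder trained 10 epochs at batch 128 with Adadelta
(decay 0.95, $\epsilon = 10^{-6}$); subnetworks fine-tuned 25 epochs with
early stopping (patience 5, best weights restored) at batch 50 with Adam
at learning rate 0.001; $n = 33$ subnetworks, selected by five-fold
cross-validation over the grid $1, 3, \dots, 37$; stratified 75/25
train/test split.  The "decay rate" listed among the method's parameters
has no published value and is left at the optimizer's own default.

Two choices the architecture figures leave open were resolved as follows.

* **Encoder/decoder dimensions.**  The encoder is an AlexNet-flavoured
  stack of five 3×3 convolution blocks (16, 32, 64, 64, 32 filters by
  default) with three 2×2 max-pooling stages — a total downsampling of 8 —
  and the decoder mirrors it with nearest-neighbour upsampling plus
  convolution, ending in a single-channel sigmoid layer.  All filter
  counts are configurable; the architecture adapts to any input size that
  is a multiple of 8, with one grayscale input channel.
* **Topper input.**  Whether the topper consumes the spatial latent block
  or a pooled vector is not recoverable from the published figures.  The
  full-scale default is global average pooling (at 224×224 the latent
  block is 28×28×32; flattening it would be a 25 088-dimensional dense
  input).  At desk scale the latent block is only 8×8, and experiments
  showed the pooled 32-vector starves the head — training sits on a long
  uniform-prediction plateau — so `desk_config()` flattens the latent
  block instead (`topper_pool = "flatten"`).
* **Early-stopping data.**  Outside cross-validation there is no held-out
  fold, so each subnetwork uses its out-of-bag samples (training images
  never drawn into its bootstrap resample, in expectation ~37 % of the
  pool) as the early-stopping validation set.  This uses no test data and
  costs nothing extra.

Seeding is a single integer with fixed stage offsets (autoencoder: seed;
subnetwork $i$: seed$+1+i$; stacking head: seed$+1000$; splits and
bootstrap: seed$+2000$), so every run is replayable bit-for-bit in
single-threaded execution.

## The synthetic generator

The original video dataset has no public accession, so the package ships a
seeded parametric generator of the six classes
(`generate_class_image()`, `generate_dataset()`).  Classes differ in
exactly the three cues an annotator uses — shape, intensity, texture — on
a mid-gray (0.5) background typical of phase-contrast crops:

| class id | recipe |
|---|---|
| 0 cell cluster | 3–6 overlapping Gaussian lobes, strong internal texture |
| 1 debris | small irregular fragment, slightly darker than background |
| 2 unattached cell | compact bright disc with a bright halo ring (+0.45 contrast) |
| 3 attached cell | large soft-edged region, very low contrast, blends into background |
| 4 dynamically blebbing | medium disc with 1–4 boundary protrusions |
| 5 apoptotically blebbing | disc ringed by 8–11 small bright blebs |

Contrasts scale with `class_separability`; `noise_sd` adds Gaussian pixel
noise on the normalized scale.  At separability 1.0 and noise 0.02 the
classes are separable by a plain 5-nearest-neighbour classifier on 16×16
pixel vectors (≥80 % held out), which is what makes the end-to-end
training checks meaningful.  The generator is deterministic in its
configuration: identical config (including seed) reproduces bit-identical
image sets.

What it does **not** emulate: phase-contrast optics (shade-off, realistic
halo physics), 10×/20× magnification mixtures, within-class hardness
(e.g. attached cells genuinely fusing with background texture), temporal
correlation between crops from one video, or class imbalance of real
assays.  Passing tests on this data therefore demonstrate that the
*pipeline learns and the ensemble behaves as designed*, not that real
hESC accuracy would be reproduced.

## Desk-scale configuration

`desk_config()` is the setting used by the package's own end-to-end
checks, sized for a single CPU: 64×64 inputs, a narrower encoder
(8, 16, 32, 32, 32 filters), 2 autoencoder epochs at batch 32, 10
fine-tuning epochs (patience 3), 15 stacking epochs, 5 subnetworks, and
the flattened topper input discussed above.  On the default synthetic
dataset (6×60 labeled + 600 unlabeled images) one full run — pretraining,
5 subnetworks, stacking, holdout evaluation — takes on the order of two
minutes and reaches held-out accuracy near 1.  Learning rate, batch size
and all other fields keep the published defaults.

## Numerical choices

* Both losses are implemented as the printed *sums*; optimizers scale
  gradients by the batch size, and per-epoch logs report the summed loss
  divided by the number of images, so logged values are per-image means.
* Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ inside both losses.
* Softmax rows are computed with max-subtraction; predicted classes break
  ties toward the lowest class index.
* Weight init: He-uniform for ReLU layers, Glorot-uniform otherwise,
  biases zero, all drawn from the stage-seeded RNG.
* Degenerate inputs fail loudly: empty pools, empty classes in any
  stratified operation, non-square or negative confusion matrices,
  normalized input where raw is required, input sizes not divisible by 8.

## Known limitations

The published full-scale results — 97.23 ± 0.94 % five-fold CV accuracy,
the validation curve peaking at 33 subnetworks, and the comparisons
against fused-CNN-triplet/ResNet/VGG/AlexNet baselines — were measured on
the original, unreleased hESC videos at GPU scale and cannot be recomputed
here; `scope_limitations()` states this programmatically.  The package
instead verifies what is verifiable: the metric arithmetic of the
published confusion matrices exactly, the split arithmetic exactly, the
loss implementations against independent oracles, and the ensemble's
accuracy and variance behaviour on seeded synthetic data.
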