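---
title: "Channel-attention volumetric segmentation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-attention volumetric segmentation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(segchanet)
```

## The problem

Lung tumors occupy a tiny fraction of a chest CT volume, their intensity
overlaps that of vessels and soft tissue, and their boundaries matter
clinically. This package implements a family of three-dimensional
encoder-decoder networks for voxelwise tumor segmentation from CT, built
around a channel-attention feature-fusion block, together with everything
needed to run and judge such a model: the CT preprocessing chain, the
compound training losses, volumetric overlap and surface metrics, a
seeded training protocol, and a synthetic thorax-phantom generator that
stands in for patient data.

All of the numerical machinery — same-padded dilated convolutions,
pooling, trilinear resampling, batch normalization, a reverse-mode
differentiation tape, and Adam — is implemented inside the package (R
with compiled im2col/GEMM kernels). No external deep-learning runtime is
involved, which keeps every computation inspectable and exactly
reproducible under a seed.

## The channel attention module

The fusion block combines a low-level feature map $X_L$ (high resolution,
early in the encoder) with a high-level map $X_H$ (coarse resolution,
semantically rich). With $g(\cdot)$ global average pooling,
$\mathrm{conv}_3$ a same-padded $3^3$ convolution mapping $X_L$ to $X_H$'s
channel count $c$, and $\mathrm{conv}_1$ a $1^3$ convolution:

$$X_L' = \mathrm{conv}_3(X_L), \qquad
  X_{gL}[k] = \mathrm{conv}_1(X_L')[k] \cdot g(X_H)[k], \quad k = 1 \dots c,$$
$$X_\mathrm{cam} = X_{gL} + \mathrm{up}(X_H),$$

where $\mathrm{up}(\cdot)$ is bilinear (2D) or trilinear (3D)
interpolation to $X_L$'s grid. The pooled vector acts as one scalar gate
per channel: global context selects which low-level channels to pass.
Three choices here were genuinely open and are fixed as follows:

* **No activation on the gate.** The equations as printed apply no
  sigmoid or softmax to $g(X_H)$, so none is applied by default;
  `cam_gate_activation = "sigmoid"` is available for bounded gating.
* **Channel counts.** $\mathrm{conv}_3$ maps $c_L \to c_H$ and
  $\mathrm{conv}_1$ maps $c_H \to c_H$, the unique assignment under which
  the additive fusion type-checks.
* **Pooling.** "Global pooling" is global *average* pooling; max pooling
  is never mentioned in the source description of the block.

## The three architectures

`build_segchanet()` is the main network: `depth` encoder levels of
(conv–BN–leaky-ReLU) ×2 joined by $2^3$ max pooling, a stack of dilated
convolutions at the deepest level whose rates double from 1
(`dilation_schedule`), and a mirror decoder with 2× upsampling. Each
encoder-to-decoder connection passes through the attention block when
`use_cam = TRUE` and is concatenated plainly otherwise. With
`deep_supervision = TRUE` every decoder output is upsampled to full
resolution and concatenated before the $1^3$ sigmoid head.

`build_unet()` is the plain baseline (ReLU, no normalization, skip
concatenation, sigmoid head); `build_vnet()` is the residual baseline
(channel-preserving residual stages, stride-2 downsampling convolutions
instead of pooling, additive skips, softmax head over two classes).

Design decisions worth knowing:

* **Depth semantics.** `depth` counts encoder levels including the
  deepest, i.e. `depth - 1` downsamplings; inputs must be divisible by
  `2^(depth-1)` with at least 2 voxels left at the bottom. This leaves
  the deepest map room for the dilated stack: at depth 4 on a 128-cube
  the deepest map is 16 wide and holds the default (1, 2, 4) stack whose
  receptive field is 15. A reduced depth-3 configuration on a 32-cube
  uses schedule (1, 2) (receptive field 7 on an 8-wide map); the forward
  pass refuses a stack wider than its map rather than silently saturating.
* **Same padding everywhere.** Strictly unpadded convolutions would
  force crop-and-copy plumbing and break the fixed cubic grid of the
  preprocessing contract; all convolutions preserve spatial shape.
* **Head initialization.** Sigmoid heads start at the logit of a 1%
  foreground prior rather than at 0.5. Tumor voxels are rare, and a 0.5
  start spends the first chunk of optimization relearning the background
  rate; prior initialization removes that phase without affecting what
  the network can represent.
* **Batch normalization.** Training uses the sample's own statistics
  (minibatches are assembled by gradient accumulation), inference uses
  running averages with momentum 0.1. Ties at the decision threshold go
  to background (`prob > threshold`), fixed for reproducibility.

## Preprocessing and augmentation

`preprocess_case()` applies, in order: Hounsfield-unit truncation to
[-1000, 400] (air to soft tissue; dense bone carries no tumor signal),
per-scan z-normalization to zero mean and unit *population* variance
(the population/sample distinction is immaterial at volume scale but is
fixed so exact tests are possible), and resampling to a cubic grid —
trilinear for images, nearest-neighbor for masks so no new label can
appear. Augmentation draws, per case and epoch: a left-right mirror
(p = 1/2), an intensity negation of the normalized volume (p = 1/2;
"white-to-black inversion" has no stated formula, and negation is the
interpretation that preserves zero mean and unit variance), and an
in-plane rotation uniform in ±10°, applied identically to volume
(linear, padded at the volume minimum — clipped air after normalization)
and mask (nearest, padded with background).

## Losses

Two compound objectives are provided, both on soft predictions with
smoothing $\epsilon$ (default 1) in numerator and denominator:

* `loss_iou_dsc()`: $2 - (\mathrm{IOU} + \mathrm{DSC})$, in $[0, 2]$.
  The printed form of this loss is ambiguous about bracketing; the
  reading $2 - (\mathrm{IOU} + \mathrm{DSC})$ is adopted because the
  alternative increases with better overlap and cannot be a loss.
* `loss_dice_bce()`: soft Dice loss plus mean binary cross-entropy, with
  predictions clamped to $[10^{-7}, 1 - 10^{-7}]$. This is the default
  training objective.

Both have analytic gradients used by the trainer and verified against
finite differences in the test suite.

## Metrics

`evaluate_case()` reports Dice, IOU (identically the Jaccard index),
sensitivity, specificity, precision, voxel accuracy, the symmetric
Hausdorff distance in physical mm, and the normalized surface distance
at a 4 mm default tolerance. Surfaces are foreground voxels with at
least one 6-neighbor background voxel (array boundaries count as
background); distances are between voxel centers. Degenerate cases
follow the perfect-agreement convention: two empty masks score Dice =
IOU = NSD = 1, one empty mask scores 0 with an undefined (NA) Hausdorff
distance. Published tables in this literature occasionally print Jaccard
values exceeding Dice, which is impossible under these definitions; the
standard definitions are implemented and such tables are not used as
oracles.

## The phantom generator

`generate_phantom()` builds a geometric thorax: an air background at
-1000 HU, a soft-tissue body ellipsoid (40 ± 20 HU), two lung ellipsoids
(-800 ± 50 HU), a tubular trachea splitting into two bronchi, and
spherical tumor nodules (30 ± 15 HU) with diameters drawn from 5–32 mm —
the size range of screening-detected lung nodules — placed strictly
inside the lungs, plus additive Gaussian acquisition noise. The paired
mask marks nodules only. The default desk-scale grid is a 64-cube at
1.5 mm spacing; training experiments in the tests use a 32-cube at 3 mm.

What the phantom does *not* emulate: CT reconstruction physics,
juxtapleural and juxtavascular nodule context, irregular margins
(a union-of-spheres option approximates lobulation), respiratory motion,
or inter-scanner variability. Passing phantom benchmarks therefore
demonstrates that the pipeline is implemented correctly and can learn
and localize rare bright structures — not that the network reaches any
particular accuracy on patient data.

## Training protocol

`train_model()` runs Adam (defaults: learning rate 5e-4, the canonical
nine-point grid over \{1e-4, 1e-3, 3e-3\} × minibatch \{2, 4, 8, 12\} is
in `segchanet_grid()`), monitors validation binary cross-entropy, and
multiplies the learning rate by 0.1 whenever the monitor fails to
improve for 15 consecutive epochs (patience counter resets after each
cut; the rate never increases). Early stopping is deliberately not
implemented — it is not part of the stated protocol. All randomness
(shuffling, augmentation) flows from one seed; identical calls give
identical histories. When no validation cases are supplied the monitor
falls back to the epoch's own training BCE rather than spending an extra
inference pass.

Ensembling follows the 5-fold majority-vote scheme: `kfold_assign()`
partitions cases so each appears in exactly one validation fold, and
`ensemble_majority_vote()` marks a voxel foreground iff strictly more
than half of an odd number of member masks do. `gradcam_heatmap()`
provides gradient-weighted channel pooling at any named layer, rectified
and max-normalized, for qualitative inspection of what drives the
prediction.

## Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` exercise the full pipeline at
sizes chosen to make a complete run practical on a single CPU while
still being non-trivial learning problems: metric and fusion oracles on
8-cubes; a single-phantom overfitting run (depth-3, base-8 attention
network on one 32-cube phantom, 250 Adam steps at lr 1e-3), which
reaches a soft Dice well above 0.95; and a generalization run (16
training phantoms, 4 held-out, 15 epochs at minibatch 2 — an
optimization budget comparable to the overfitting run) reported for both
the attention and plain-skip variants side by side. The attention
variant carries the quantitative bound; the plain variant's score is
reported to record the direction of the attention gain at toy scale
without asserting it, since a 20-phantom experiment cannot resolve small
architecture differences reliably.

## Known limitations

* Minibatch statistics are per-sample; very large minibatches do not
  give the usual batch-normalization variance reduction.
* Nearest-neighbor upsampling has no gradient path (unused by the
  provided architectures, which upsample linearly).
* The Hausdorff distance is the exact maximum, not the robust 95th
  percentile variant.
* 2D operation is supported throughout the fusion block and U-Net but
  the volumetric path is the primary, tested configuration.
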