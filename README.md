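# segchanet

Three-dimensional lung-tumor segmentation from CT in R: an
encoder-decoder network with **channel-attention feature fusion**
(SegChaNet), U-Net and V-Net baselines, the standard CT preprocessing
chain, compound segmentation losses, volumetric evaluation metrics, a
seeded training protocol with majority-vote ensembling and Grad-CAM, and
a synthetic thorax-phantom generator so the entire pipeline runs — and is
tested — on a single CPU without patient data.

The package is for researchers who want an inspectable, dependency-light
reference implementation of channel-attention segmentation: every
numerical component (im2col/GEMM convolutions, trilinear resampling,
batch normalization, reverse-mode differentiation, Adam) is implemented
in the package itself (R + compiled kernels), so nothing is hidden
behind a deep-learning runtime.

## The model

The channel attention module (CAM) fuses a high-resolution low-level
feature map `X_L` with a coarse high-level map `X_H`:

    X_L' = conv3(X_L)                        # 3x3x3, c_L -> c channels
    X_gL[k] = conv1(X_L')[k] * g(X_H)[k]     # per-channel scalar gate
    X_cam = X_gL + up(X_H)                   # trilinear upsampling

where `g(.)` is global average pooling. Globally pooled semantic context
gates which fine-scale channels survive; the fused map feeds each
decoder level. The surrounding network has four encoder/decoder levels
of (conv–BN–leaky ReLU)×2 by default, a dilated-convolution stack with
doubling rates at the bottleneck, 2× upsampling decoders, optional deep
supervision (all decoder outputs upsampled and concatenated before the
head), and a sigmoid voxel head thresholded at 0.5.

Training uses the Dice + binary cross-entropy compound loss (a
`2 − (IOU + DSC)` variant is also provided), Adam, and a
reduce-on-plateau schedule (×0.1 after 15 stagnant epochs of validation
BCE). Evaluation reports Dice, IOU/Jaccard, sensitivity, specificity,
precision, accuracy, Hausdorff distance (mm) and normalized surface
distance at 4 mm.

## Worked example

Generate a thorax phantom, preprocess it, train a reduced attention
network on it, and score the prediction:

```r
library(segchanet)

spec <- phantom_spec(shape = c(32, 32, 32), spacing = c(3, 3, 3),
                     nodule_diameter_mm = c(8, 25), nodules_per_case = c(1, 2))
ph <- generate_phantom(spec, seed = 11)
case <- preprocess_case(ph$volume, ph$mask,
                        preprocess_config(target_shape = c(32, 32, 32)))

set.seed(11)
net <- build_segchanet(network_config(depth = 3, base_channels = 8,
                                      dilation_schedule = c(1, 2)))
fit <- train_model(net, list(case),
                   train_config(initial_lr = 1e-3, minibatch = 1,
                                epochs = 120, seed = 11))
pred <- predict(fit, case$volume, type = "mask")
evaluate_case(pred, case$mask, tolerance_mm = 4)
```

which prints:

```
<phantom_case> 32x32x32 voxels, 2 nodule(s), seed 11
<segchanet> 3D, depth 3, base 8 channels, CAM on
  parameters: 154353; head: sigmoid (1 class)
<seg_fit> segchanet trained 120 epoch(s) on 1 case(s) (0 validation)
  final: train loss 0.0644, monitored BCE 0.0010, lr 1.00e-03
dsc 1.0000  iou 1.0000  sens 1.0000  spec 1.0000  prec 1.0000  acc 1.0000
hausdorff 0.000 mm  nsd 1.0000
```

After 120 Adam steps the network reproduces the two-nodule ground truth
voxel for voxel on its training case: Dice and IOU of 1, a Hausdorff
distance of 0 mm, and every surface point within the 4 mm NSD tolerance.
Held-out performance is measured by `phantom_generalization()`, which
trains on 16 phantoms and evaluates 4 unseen ones, for both the
attention and plain-skip variants.

A command-line wrapper (`inst/cli/segchanet`) exposes the workflow as
`simulate`, `preprocess`, `train`, `predict`, `evaluate`, `ensemble` and
`gradcam` subcommands over YAML configs; see `?seg_main`.

## Package layout

- `R/` — volume I/O (NIfTI, MetaImage, CSV manifests), preprocessing and
  augmentation, the CAM block, the three architectures, losses, metrics,
  training/ensembling/Grad-CAM, phantom generation, CLI.
- `src/` — compiled kernels: dilated same-padded convolutions with exact
  gradients, max pooling, linear/nearest resampling, surface-distance
  search.
- `tests/testthat/` — unit and property tests per module plus an
  end-to-end acceptance suite with brute-force oracles.
- `vignettes/segchanet-methods.Rmd` — the model, every tunable with its
  default and rationale, what the phantom does and does not emulate, and
  known limitations.
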