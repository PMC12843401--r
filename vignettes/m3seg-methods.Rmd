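---
title: "Model and methods behind m3seg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind m3seg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m3seg)
```

## The problem and the architecture

m3seg segments 2D medical images (CT slices, endoscopy frames, X-rays, skin
photographs) into multiple anatomical classes. It implements a hybrid
U-shaped encoder–decoder in which a convolutional stem supplies local detail
and a transformer stack supplies global context, with four attention
mechanisms threaded through the network:

* **MSGA** (multi-scale gate attention) splits the token-grid channels into
  `G` subgroups. Each subgroup is passed through a 3×3 depthwise convolution
  gated by a coordinate-attention–style spatial map (sigmoid of the fused
  directional average/max pooling strips), then re-weighted by a
  cross-spatial interaction: a group-normalized stream and a raw stream
  exchange information through channel-softmaxed global descriptors and
  matrix products, and the fused map, squashed by a sigmoid, multiplies the
  original subgroup. Because the final gate is a sigmoid, MSGA can attenuate
  but never amplify — a property the test-suite asserts.
* **ME-MSA** (Manhattan-enhanced multi-head self-attention) subtracts a
  learnable multiple of the normalized Manhattan distance between token
  coordinates from the attention logits: per head,
  `Softmax(QKᵀ/√d_k − λ·D)V`, with `D_ij = (|x_i−x_j|+|y_i−y_j|)/(H+W)` and
  λ initialized to 1. The bias acts as a soft locality prior; with λ = 0 the
  code path is exactly vanilla attention.
* **MKGAG** (multi-kernel group attention gate) filters each skip
  connection: three independent 3×3 group-convolution + batch-norm branches
  are summed, passed through ReLU6 and a 1×1 convolution to a single
  channel, and the sigmoid of that map re-weights every channel of the skip
  feature identically.
* **MSSA** (multi-scale selective attention) refines decoder features with
  four depthwise-separable branches (kernels 3/5/7/9, each ReLU +
  squeeze-and-excitation), concatenation and 1×1 fusion, followed by
  linear-complexity Performer attention over the spatial tokens and a 1×1
  recombination, with a residual connection to the stage input.

The decoder follows a merge–augment–upsample schedule: bilinear 2×
upsampling, concatenation with the MKGAG-gated skip, 3×3 fusion, MSSA. A
1×1 convolution produces per-pixel logits at the input resolution.

## Losses and metrics

Training minimizes `L = λ₁·CE + λ₂·Dice` with λ₁ = λ₂ = 0.5: cross-entropy
provides smooth per-pixel gradients, the Dice term directly optimizes
foreground overlap and counterbalances class imbalance. The Dice average
runs over the `C − 1` foreground classes (background excluded), smoothed
with ε = 1e−5 in numerator and denominator. Reported metrics are DSC (as a
percentage), IOU, and the 95th percentile Hausdorff distance computed from
boundary voxels (foreground with a background face-neighbor), scaled by the
physical spacing, pooling both directed distance sets before taking the
percentile. When either mask is empty HD95 is undefined; such cases are
excluded from means and counted rather than imputed.

## Differentiation engine

No neural-network framework is used: the package carries its own
reverse-mode automatic differentiation over plain R arrays, with the
compute-heavy kernels (im2col/GEMM convolution and its backward pass,
bilinear upsampling, warping, surface distances) in C++ via Rcpp /
RcppArmadillo. Every operation is dual-mode — with no active tape it simply
computes values — so the identical forward code serves training and
inference. All operation gradients are verified against central finite
differences in the test-suite.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `input_size` | 224 px | square input side |
| `patch_size` | 16 px | token patch; grid is `(S/P)²` tokens, so 196 at defaults, 49 at P = 32, 784 at P = 8 |
| `hidden_dim` / `depth` | 768 / 12 ("base"); 1024 / 24 ("large") | transformer width and depth |
| `msga_groups` | 8 | channel subgroups of MSGA (per-group width ≥ 64 at base scale) |
| `decoder_channels` | 256/128/64/16 | up-stage widths, skips on the first three |
| `performer_features` | 256 | random features `m` of the linear attention |
| `lambda_init` | 1.0 | initial Manhattan bias strength per head |
| optimizer | SGD, lr 0.01, momentum 0.9, weight decay 1e−4 | polynomial lr decay, power 0.9 |

The `tiny` preset (64 px input, width 64, depth 2, G = 4, m = 64, stem
widths 8/16/32, decoder 32/16/8/8) exists so that the complete network —
every module on the gradient path — can be trained on one CPU core in
minutes; it is the configuration used by the examples and the test-suite.

## Design choices made where the design was open

* **CNN stem.** A residual three-stage backbone (stride-2 convolution +
  instance norm + ReLU, then a two-convolution residual block per stage)
  emitting skips at 1/2, 1/4 and 1/8 resolution; the 1/8 features are
  patch-embedded by a strided convolution so the token grid is `S/P`.
* **Normalization.** Samples are processed singly and gradients accumulated
  over the batch, so batch statistics would degenerate to per-sample
  statistics anyway. The stem and decoder therefore use instance
  normalization — per-channel spatial statistics of the current sample at
  training and inference alike, the batch-size-independent convention of
  small-batch medical segmentation. MKGAG keeps true batch normalization
  with running statistics (momentum 0.1) used at evaluation, matching its
  published formulation; its tests pin the statistics explicitly where
  exact values matter.
* **Directional pooling in MSGA.** Average- and max-pooled strips along
  each axis are concatenated per direction and reduced by a 1×1 projection
  shared between directions; the two reduced strips are broadcast-added
  into an `H×W` map before the sigmoid.
* **Cross-spatial interaction.** Stream A is the group-normalized gated
  feature; stream B is the raw gated feature. Each stream's channel-softmaxed
  global average descriptor multiplies the other stream's flattened map; the
  two 1×N maps are added, sigmoid-squashed and broadcast over channels.
  The group count of the internal group norm is `gcd(G, C/G)`.
* **λ structure.** One learnable scalar per attention head, initialized to
  1.0 and unconstrained in sign during training.
* **Residual source.** The attention sub-block residual is taken from the
  block input (pre-MSGA), standard pre-norm style.
* **MKGAG group count.** `gcd(4, C)` for the 3×3 group convolutions; all
  three branch kernels are 3×3.
* **Performer feature map.** The positive softmax-kernel map
  `ϕ(x) = exp(ω·x̂ − ‖x̂‖²/2)/√m` with `x̂ = x/d^{1/4}` and Gaussian `ω`,
  drawn once at module construction from a seeded generator so forward
  passes are deterministic; a shared max-shift keeps the exponentials
  finite and cancels in the row normalization. Attention runs post-fusion
  (a single pass over the fused multi-scale features).
* **Recombination.** The attention output is concatenated with the fused
  features (2C) and projected back to C by a 1×1 convolution, plus a
  residual to the stage input.
* **SE blocks.** Reduction ratio 16 with a floor of 4 bottleneck channels.
* **Upsampling.** Bilinear with half-pixel centers (corner alignment
  disabled); label masks are never interpolated — they are resampled
  nearest-neighbor wherever geometry changes.
* **Augmentation magnitudes** not fixed by the training protocol use
  conservative defaults: translation ≤ 10 % of the side, scale 0.9–1.1,
  elastic α = 30 / σ = 5 px, ≤ 2 occlusion holes of ≤ 16 px, brightness /
  contrast ± 0.2, Gaussian noise σ ≤ 0.02, CLAHE clip 2.0; each optional
  transform fires with probability 0.5, the flip probability and ± 20°
  rotation limit follow the stated protocol. Geometric transforms are one
  joint inverse-mapped warp (bilinear for the image, nearest for the mask),
  so image and mask displace identically.
* **Seeding.** One master seed fans out to parameter initialization,
  feature draws, batch sampling and augmentation; per-iteration seeds are
  derived from (seed, iteration), which makes checkpoint resume bitwise
  identical to an uninterrupted run.

## The phantom generator

`generate_phantom()` draws `C − 1` organ-like blobs — randomly oriented
ellipses with low-order radial harmonics — on a noisy background with a
slow intensity drift. Blob areas are log-spaced from > 10 % of the canvas
down to < 1 % (the multi-scale guarantee the tests assert over 100 seeds),
each class has a distinct mean intensity, and two intensities are
deliberately close to create a low-contrast pair. The mask equals the blob
geometry exactly and every label is present.

The generator emulates the qualitative difficulties of abdominal CT slices
— targets of very different sizes, smooth irregular outlines, low contrast,
noise — but not real anatomy, scanner physics, partial-volume effects or
inter-slice correlation. Passing the end-to-end tests therefore shows that
the architecture, losses, gradients and optimization interact correctly,
not that the model reaches any particular accuracy on clinical data.

## Problem sizes used by the tests

Unit tests run on grids of a few dozen pixels. The end-to-end learnability
check trains the `tiny` preset on four 64-px, 4-class phantoms with batch
size 2 for at most 2,000 iterations (stopping early once the mean
foreground training DSC reaches 0.90; up to three initialization seeds are
allowed, since success depends on the initialization draw). The kernel
attention oracle uses N = 64 tokens, d = 16, feature counts 16–1024 and 20
draws each.

## Known limitations

* 2D slices only; no volumetric (3D) model.
* No pretrained backbone weights are shipped or downloaded; benchmark-scale
  accuracy requires GPU-scale training on real datasets, outside the scope
  of this package.
* The training loop processes samples singly; with large batch sizes the
  gradient accumulation is exact but wall-clock cost grows linearly.
* DICOM input is unsupported (NIfTI and PNG only; HU windowing is applied
  only when the caller requests it).
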