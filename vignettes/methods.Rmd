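---
title: "Model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypseg)
```

## The segmentation problem

Colorectal polyps protrude from the colonic mucosa but often share its
color and texture; under endoscopic illumination their borders are blurred
by mucus and specular reflections. `polypseg` implements a convolutional
encoder–decoder that maps an RGB endoscopy frame to a per-pixel polyp
probability map, together with the compound loss used to train it, the six
measures used to evaluate it, the paired augmentation/splitting protocol,
and a synthetic image generator that lets the whole pipeline run and be
tested on one CPU with no external data.

Because no deep-learning framework is available to this package's target
environment as an R dependency, the network is built on the package's own
reverse-mode autodifferentiation tape (`R/autograd.R`) with compiled
`im2col`/`col2im`, pooling and bilinear-resampling kernels under `src/`.
Convolutions reduce to BLAS matrix products; every operator's analytic
gradient is validated against central finite differences in the test
suite.

## Architecture

**Encoder.** A HarDNet68 harmonic-dense backbone: a two-conv stem (widths
32, 64; the first conv has stride 2), then five harmonic dense blocks
(HDBs) with stage plan $(n, k, t)$ = (8, 14, 128), (16, 16, 256),
(16, 20, 320), (16, 40, 640), (4, 160, 1024) and global multiplier
$m = 1.7$. Inside a block, layer $l$ receives the concatenation of the
outputs of layers $l - 2^i$ for every $2^i$ dividing $l$ (`link_targets()`),
and a layer's width is $k \cdot m^{v}$ with $v$ the 2-adic valuation of its
index, rounded to the nearest even integer (`layer_width()`). The block
output concatenates the final and all odd-indexed layers and is compressed
by a 1×1 transition to $t$ channels. Stages 1, 2, 4 and 5 are entered
through a 2×2 max pool, so the tapped outputs of stages 1, 3, 4 and 5 form
a stride-4/8/16/32 pyramid with 128/320/640/1024 channels. Two blocks run
at stride 8; the deeper one (t = 320) feeds the decoder skip, since it is
the stage's final representation.

**Bridge.** A DenseASPP module on the stride-32 map: four 3×3 branches
with dilations 3, 6, 12, 18, each preceded by a 1×1 reduction; branch $i$
consumes the input concatenated with all previous branch outputs, and a
final 1×1 projection fuses input plus branches. Widths are tied to the
input width $C = 1024$: reduction $C/8 = 128$, branch growth $C/4 = 256$,
projection $C/2 = 512$. This is the DenseASPP-style two-conv branch rather
than a single wide dilated conv: direct 3×3 branches at width $C/4$ on a
1024-channel input would alone cost ~13M parameters and push the model far
past its intended ~23M total, so the budget fixes this reading.

**Decoder.** Three stages. Each bilinearly upsamples the stream 2×,
matches the encoder skip (strides 16, 8, 4) to the stream width with a 1×1
conv, multiplies the two elementwise, applies the spatial–channel
attention (SCA) module, and finishes with a 3×3 conv to the next stream
width (512 → 256 → 128 → 64). The elementwise product is the natural
reading of a "dot product" between feature maps that must preserve spatial
layout; a true inner product would collapse the map. A 1×1 conv to one
channel, a sigmoid, and a bilinear 4× upsample to the input size produce
the probability map. Only this final output is supervised.

**SCA.** Spatial attention pools across channels (per-pixel max and mean),
concatenates the two maps, and a 1×1 conv + sigmoid yields weights
$M_s \in (0,1)^{1 \times H \times W}$ that rescale the input. Channel
attention pools across space (global max and average), sends both vectors
through the *same* three-layer 1×1 bottleneck $C \to C/8 \to C/8 \to C$,
concatenates and maps $2C \to C$, and a sigmoid yields
$M_c \in (0,1)^{C \times 1 \times 1}$. The two pooling directions are
forced by the declared weight shapes. The bottleneck is a linear chain —
three stacked 1×1 transforms with biases and no interleaved activation,
kept exactly as specified even though a two-layer ReLU bottleneck is the
more common design. The two attended tensors are concatenated ($2C$) and
fused back to $C$ by a 1×1 conv + batch norm + ReLU; the fusion layer is
this package's choice for returning to $C$ channels, which the original
description leaves open.

With all of these choices the assembled 256×256 network holds **22.94M**
trainable parameters, within 0.8% of the ~23.11M target that pinned the
open widths.

## Loss

The training objective is the unweighted sum of two terms (weights are
configurable):

* **Dice loss** $1 - (2\sum p t + s)/(\sum p + \sum t + s)$, computed per
  image and averaged over the batch; ranges over $[0,1]$; with $s = 0$ and
  both masks empty it is defined as 0. Default smoothing $s = 1$.
* **Focal loss** $-\alpha_t (1 - p_t)^\gamma \log p_t$ averaged over
  pixels, with $p_t$ the probability assigned to the true class and
  $\alpha_t = \alpha$ (foreground) / $1-\alpha$ (background). Defaults
  $\alpha = 0.25$, $\gamma = 2$, the established focal-loss values, since
  the source names but never fixes them. Setting $\alpha = 1$ disables
  class weighting entirely (both classes weighted 1), so
  $\gamma = 0, \alpha = 1$ reduces exactly to mean binary cross-entropy;
  with the switched form $\alpha = 1$ would silence the background term,
  which is never useful. Probabilities are clamped to
  $[10^{-7}, 1-10^{-7}]$ before the logarithm.

## Evaluation measures

Per image, from the pixel confusion counts of the mask binarized at 0.5:
Dice $2TP/(2TP+FP+FN)$, IoU $TP/(TP+FP+FN)$, sensitivity $TP/(TP+FN)$,
specificity $TN/(TN+FP)$; each averaged over the evaluation set. The
printed source formula for sensitivity duplicates the IoU expression; the
standard $TP/(TP+FN)$ is implemented, as the surrounding prose describes.
Degenerate denominators score 1 (a prediction cannot be faulted on pixels
that do not exist). The structure measure
$S = \alpha S_O + (1-\alpha) S_R$ with $\alpha = 0.5$ follows the
reference construction: an object-aware term comparing foreground and
background prediction statistics against the ground-truth regions, and a
region-aware term splitting both maps into four quadrants at the
ground-truth centroid and combining SSIM-style statistics with area
weights; all-background ground truth scores $1 - \bar p$ and
all-foreground scores $\bar p$. S-measure and MAE consume the raw
probability map (the structure-measure convention); the count-based
measures consume the binarized mask.

## Data protocol

Input pairs are an RGB image and a PNG mask binarized at 127/255; all
images are resized to 256×256 (bilinear for images, nearest for masks).
Records are split 80/10/10 into train/validation/test by a seeded shuffle,
with `round(n f)` for the two small splits and the remainder to train.
Splitting happens before augmentation, at the source-image level, so no
augmented variant of one image can land in two splits.

Each training image is expanded into 20 variants. The augmentation
operations are a rotation up to ±30°, a 160×160 center crop, and a 3×3
Gaussian blur, but their composition into 20 distinct variants is not
prescribed; here each variant draws an independent chain — rotation always
(angle uniform in ±30°), crop-then-resize-back with probability 1/2, blur
(image only) with probability 1/2 — seeded per (record, variant index), so
augmentation is bit-reproducible. Augmentation runs at the record's native
size with the resize applied last. The blur sigma is not stated with the
kernel; the usual kernel-derived default $0.3((k-1)/2 - 1) + 0.8 = 0.8$
is used and exposed in the config.

## Synthetic data

`synth_generate()` emulates the *structure* of public polyp benchmarks:
low-frequency pink/red mucosa backgrounds (bilinearly upsampled coarse
Gaussian fields), 1–3 elliptical lesions jointly covering 8–35% of the
frame (chosen to match the benchmarks' typical single-digit-to-third
foreground fractions), low-contrast lesion hue shifts, Gaussian-feathered
lesion borders with a crisp pre-feather mask, and specular highlight
speckles. It does **not** reproduce real colonoscopy geometry (lumen
perspective, folds, vignetting), instrument artifacts, or the shape
diversity of real polyps — so tests passing on synthetic data demonstrate
that the pipeline and optimization behave correctly, not that the trained
weights transfer to clinical images.

## Training engine

Adam (lr $10^{-4}$, $\beta = (0.9, 0.999)$), batch size 4, up to 300
epochs, early stopping once the validation metric has not improved for 50
consecutive epochs, returning the best-validation weights. "Validation
accuracy" is monitored as validation mDice, the headline measure.
Improvement is strict (`>`); ties count toward patience. No learning-rate
schedule and no gradient clipping are applied. All randomness (weight
init, shuffling, splits, augmentation) descends from explicit seeds;
training trajectories reproduce bit-for-bit on one CPU.

## Numerical choices

* Conv layers are Conv → BatchNorm → ReLU (momentum 0.1, eps $10^{-5}$;
  biased variance for normalization, unbiased in the running estimate).
  Convs carry no bias under batch norm.
* Weight init is Kaiming-uniform (fan-in), biases zero, from a seeded RNG.
* All convs zero-pad to "same" size; dilated convs pad by their dilation.
* Downsampling is a 2×2 max pool; upsampling is bilinear with half-pixel
  centers (`align_corners = false` convention), including the final 4×.
* Sigmoid outputs are clamped to $[10^{-12}, 1-10^{-12}]$: the true
  sigmoid never reaches its endpoints but doubles saturate past
  $|z| \approx 37$, and the attention and probability contracts promise
  open-interval values.
* Channel-attention bottleneck width is $\lceil C/8 \rceil$ so small toy
  widths remain usable; the canonical widths are all divisible by 8.
* Global max pooling breaks ties by first index; 2×2 max-pool windows are
  disjoint so the backward scatter is exact.

## Problem sizes used by the tests

The test suite and acceptance script exercise the full-width canonical
network only where training is not required (parameter counting, shape
propagation at 64–256 px). Optimization behavior is demonstrated on a
width-reduced preset with the same five-stage topology
(`network_spec_tiny()`): the learnability check fits 8 synthetic 96×96
pairs for at most 200 Adam steps (batch 4, lr $10^{-3}$) and requires
training mDice ≥ 0.95, which it reaches in a few CPU seconds. The
augmentation-arithmetic check runs the full 800 × 20 and 490 × 20 counts
at 96×96 with a 64×64 crop, since the canonical 160×160 crop is defined
only for larger frames.

## Known limitations

* CPU-only; practical for the tiny preset and for inference-scale use of
  the canonical network, not for full 300-epoch 256×256 training.
* Binary segmentation only; no multi-class head, no deep supervision, no
  test-time augmentation.
* The synthetic generator's gap to real colonoscopy data (above) means
  benchmark-level accuracy claims are out of scope here; the package
  verifies mechanism, contracts and trainability.
* No ImageNet pretraining: encoders start from random weights.
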