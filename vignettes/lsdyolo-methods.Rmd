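---
title: "Detecting lemon surface disease with a configurable YOLOv8-style model family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lemon surface disease with a configurable YOLOv8-style model family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Orchard photographs of lemon trees contain between one and six fruit per
frame, photographed at varying distances, under leaf shade, back light and
partial occlusion.  The detection task is two-class: localise every lemon
and decide whether its surface carries disease.  `lsdyolo` implements a
family of anchor-free single-stage detectors for this task on CPU, centred
on LSD-YOLO: a nano-scale YOLOv8-style baseline extended with three
modifications that can be toggled independently, yielding the eight ablation
architectures of a full factorial grid:

* **SAC** — switchable atrous convolution in the backbone (a standalone
  SAConv after the stride-4 downsample, and C2f-SAC blocks replacing C2f at
  the stride-4 and stride-16 stages);
* **CBAM** — convolutional block attention at five documented sites;
* **SOD** — a stride-4 (P2) feature-fusion path with a fourth detection
  head for small targets.

All tensor kernels (im2col convolution with single-precision GEMM, fused
batch-norm/SiLU, pooling, the full backward pass) are implemented in the
package via Rcpp/RcppArmadillo; no external deep-learning runtime is used.

## The baseline detector

The baseline is the public nano-scale layout: a stem convolution and four
backbone stages of stride-2 convolution + C2f blocks (depth multiple 0.33
giving 1/2/2/1 bottlenecks, width multiple 0.25 giving 16/32/64/128/256
channels), an SPPF block, a top-down + bottom-up (FPN+PAN) neck, and a
decoupled head with distribution-focal box regression (`reg_max` = 16) and
per-class sigmoid scores.  At a 640×640 input the neck emits feature maps at
80×80, 40×40 and 20×20 (strides 8/16/32); the stride-16 width is 512
pre-scaling (we read the occasionally-quoted 516 as a typo — channel widths
in this family are powers of two).  With two classes this baseline counts
3,011,222 trainable parameters (3.01 M).  Parameter counting includes every
trainable scalar — convolution kernels, attention MLPs, batch-norm affine
pairs — and excludes batch-norm running statistics and the frozen DFL
projection.

## Switchable atrous convolution and C2f-SAC

A SAC layer computes

\[ y = S(x)\cdot\mathrm{Conv}(x, w, 1) + (1 - S(x))\cdot\mathrm{Conv}(x, w + \Delta w, r) \]

where the switch \(S(x)\) is a 5×5 average pool followed by a 1×1
convolution to a single channel and a sigmoid, broadcast over output
channels.  The dilated branch uses *exactly* \(w + \Delta w\) — the weight
lock: there is no independent second kernel, and any gradient reaching the
dilated branch updates both \(w\) and \(\Delta w\).  Two global-context
modules (global average pool → 1×1 convolution → residual broadcast add)
flank the switched convolution.  \(\Delta w\) and the switch initialise to
zero, so training starts from plain-convolution behaviour with equal mixing
(\(S = 0.5\)); the atrous rate defaults to \(r = 3\) and is config-exposed
(`sac_rate`).  Within C2f-SAC the block's input transition convolution
becomes a 3×3 SAC (contexts included); the split/concat topology and the
bottlenecks are untouched, so the block is a drop-in replacement.

## Attention and the small-object path

The CBAM variant uses reduction ratio 8 in a shared, bias-free two-layer
channel MLP applied to average- and max-pooled descriptors, and a 3×3
convolution (2→1 channels) over the stacked channel-mean/channel-max maps
for spatial attention; the channel gate applies first.  The SOD variant
extends the top-down path by one upsample + concatenation with the stride-4
backbone feature (160×160×64 pre-scaling at 640 input), fuses to a
160×160×128 head input, and re-links the bottom-up path from P2 through P5,
giving four detection heads.  Because the shared head widths derive from the
narrowest level (now 32 channels instead of 64), the SOD-only variant is
*lighter* than the baseline: 2,926,808 parameters (2.93 M).

## Placement and the parameter budget

The backbone/neck insertion points are not uniquely determined by
LSD-YOLO's block diagrams alone, so we fix them by the family's reference
parameter budgets, which the package reproduces exactly:

| variant | parameters | rounded |
|---|---|---|
| baseline | 3,011,222 | 3.01 M |
| + SOD | 2,926,808 | 2.93 M |
| + CBAM | 3,078,901 | 3.08 M |
| full (SAC+SOD+CBAM) | 3,346,362 | 3.35 M |

CBAM sits after the stride-8 and stride-16 backbone taps, after SPPF, and
after the two top-down fusion concatenations (+67,679 parameters; all five
sites exist unchanged in both neck layouts, so the delta is identical with
SOD on).  SAC contributes +351,875 parameters through the standalone SAConv
and the two C2f-SAC stages.  The three deltas are exactly additive — no
insertion changes another's tensor widths — so the full model lands at
3.35 M, a 0.34 M increase over the baseline.  One consequence of exact
additivity is that the SAC-only variant counts 3.36 M; no additive placement
can make both it and the full model round to the same 3.35 M while SOD
subtracts 0.08 M and CBAM adds 0.07 M.  We prioritise the baseline, SOD,
CBAM and full-model budgets.  Both placement lists are recorded in the
variant YAML (`write_variant()`), and `count_parameters()` is exact and
invariant to input size and batch.

## Dataset handling: tiling and folds

High-resolution field images are tiled into 1024×1024 windows centred on
each annotated target and clamped to the image bounds; a target already
fully contained in a chosen window does not open a new one, so co-occurring
targets share tiles.  Labels are regenerated in window coordinates; a box
clipped by a window edge keeps its class, is clipped, and carries an edge
flag (metadata preserved in a JSON sidecar).  A clipped box is kept when at
least 30% of its area is visible (`min_visibility`, configurable — the
threshold is our choice; only the preservation of edge information is
prescribed).  For un-flagged boxes the mapping back to source pixels is
exact, which the tests assert bitwise.  Cross-validation uses k = 5 folds,
deterministic under a seed, stratified by presence of a diseased instance so
every fold sees both classes; fold sizes differ by at most one.

## The synthetic scene generator

The field dataset is private, so every pipeline stage is exercised against
a seeded synthetic stand-in that emulates its reported composition: 1–6
elliptical fruit per scene (default diseased fraction 718/5159 ≈ 13.9%,
matching the reported instance counts), dark lesion blobs on diseased
fruit (1–6 blobs, 5–30% of fruit area; disease is a property of the whole
fruit, which is how the real data are labelled), leaf-like occluders
(probability 0.3 per fruit), global illumination gain in [0.6, 1.3], and a
foliage-like background.  Ground-truth boxes bound the *visible* fruit
extent; targets more than 95% occluded are resampled.  A self-check oracle
re-detects fruit via an illumination-invariant colour mask and connected
components, and requires IoU ≥ 0.8 against every ground-truth box.

What the generator does *not* emulate: real lesion texture and colour
variability, fruit-over-fruit occlusion, bokeh and motion blur, scale
distributions of real photography.  Green tests on synthetic scenes
therefore demonstrate the correctness of the pipeline machinery and the
trainability of the architecture, not field accuracy.

## Metrics

Matching is greedy one-to-one in descending confidence: a detection is TP
iff it shares the class of, and has IoU ≥ threshold with, an unmatched
ground truth (highest-IoU unmatched one; ties by index).  Precision
TP/(TP+FP) and recall TP/(TP+FN) follow from the counts.  AP integrates the
precision–recall curve with all-point interpolation under the monotone
precision envelope (a 101-point grid is available as `method = "interp101"`);
classes without ground truth are excluded from the unweighted class mean.
mAP@50–95 averages over IoU thresholds 0.50 to 0.95 in steps of 0.05.
Across the five folds we report the mean and the *population* standard
deviation (divide by k = 5, not k − 1) — the overall-σ convention.  The AP
implementation is property-tested against a brute-force enumerator over
confidence cuts on 500 random instances.  Error visualisation follows the
conventional colouring: TP green, FN blue, FP red.

## Training

The loop is AdamW (momentum read as beta1 = 0.9, beta2 = 0.999) with initial
learning rate 0.001667, weight decay 0.0005 applied decoupled and only to
weight matrices, batch size 8, input 640×640 and 200 epochs in the full
protocol; the learning rate decays linearly to 1% of its initial value over
the run (the protocol fixes only the initial rate; linear decay is our
config-exposed default, recorded in run metadata).  The loss is the standard
anchor-free stack the family inherits unchanged: task-aligned assignment
(top-10 candidates per target among anchors whose centre lies inside it,
alignment metric score^0.5·IoU^6, conflicts resolved by IoU), BCE
classification against normalised alignment scores, CIoU box loss and
distribution-focal loss with gains 7.5/0.5/1.5.  Letterboxing pads to a
square with grey 114.  Warm-up, weight EMA and early stopping are off by
default; flips are available behind a flag and off by default, since the
protocol's only augmentation is the tiling expansion itself.  Everything is
seeded: epoch shuffles and flip draws are seeded per epoch/step, so a run
resumed from a checkpoint replays an uninterrupted run exactly (asserted in
the tests).

## Numerical choices

Convolutions compute in single precision (the customary precision of this
model family) via im2col + SGEMM; gradients accumulate per-batch in single
precision into double-precision parameter stores.  Batch norm uses eps 1e-3
and momentum 0.03 in training mode; evaluation uses running statistics.
The CIoU gradient is taken by central differences on the four box
coordinates (step 0.05 px) — the loss is smooth there and this keeps the
analytic surface small; assignment and target scores are treated as
constants of the backward pass, as is standard.  NMS is class-wise greedy
(suppress above IoU 0.7; prediction confidence 0.25, evaluation floor 0.001
with at most 300 detections per class and image — conventional settings,
config-exposed).  Degenerate inputs are defined: empty head outputs decode
to an empty detection set; images without targets contribute only
background classification loss; duplicate identical targets assign without
error.

## Problem sizes used in the checks

The self-contained checks run at deliberately small scales chosen to
exercise every code path: architecture shape contracts at 320–640 pixels,
gradient and identity checks on 6–12 pixel feature maps, tiling round-trips
on fifty 3000×2000 synthetic scenes, and an overfit check that trains the
full model on eight 256×256 scenes for 200 optimizer steps with the
protocol hyperparameters and requires train-set mAP@50 ≥ 0.8.  The overfit
check is a viability smoke test: it shows the assembled model, loss,
assigner and optimizer can fit data end to end; it does not reproduce
LSD-YOLO's reported field accuracies, which would require the private
dataset and full-scale training.

## Known limitations

* The reported field mAP values are out of reach by construction (private data,
  GPU-scale training); only architecture-intrinsic quantities are
  reproduced.
* The exact figure-level block order of the reference architecture is not
  machine-readable; placements are resolved up to the parameter-budget
  constraint and documented in the YAML.
* Single-image inference is not optimised for latency; the implementation
  favours clarity and exact accounting over speed.
* The checkpoint format is R-native (RDS); no interchange with other
  runtimes.
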