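---
title: "Architecture, accounting and training choices in bgmyolo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Architecture, accounting and training choices in bgmyolo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bgmyolo` builds and analyses a lightweight one-stage detector for plant
disease lesions: a YOLOv8n-style backbone/neck/head augmented with three
blocks — GSConv-based bottlenecks in the neck (GSC2f), a median-enhanced
channel and spatial attention block in the backbone (MECS), and a
softmax-gated multi-scale fusion module at the neck's junctions (BFM).
This vignette records the model assumptions, the parameters that matter,
the numerical conventions, and the design choices made where the published
description of the BGM-YOLO family leaves the design open.

## The detection problem and the base architecture

Lesions on leaves and fruit are small (bounding boxes from a few hundred to
a few thousand pixels at 640 px resolution), numerous disease classes look
alike, and field imagery has cluttered soil/vegetation backgrounds under
variable illumination. The base network is the "n"-scale member of the
YOLOv8 family: a strided stem, four C2f backbone stages (channel widths
64–1024 scaled by 0.25, capped at 1024), an SPPF pooling block, a PAN neck
with two top-down and two bottom-up fusions, and a decoupled anchor-free
head that emits, per cell of the stride-8/16/32 grids, one classification
logit per class and a 16-bin discrete distribution per box side
(`reg_max = 16`). Boxes are decoded as the expectation of the softmaxed
side distributions, scaled by the stride. All convolutions are
conv → batch-norm → SiLU unless a block states otherwise.

## The three blocks

**GSConv / GSC2f.** GSConv halves the output width with a standard
convolution, refines that half with a depthwise convolution of the same
kernel size, concatenates the two halves, and shuffles channels in two
groups (reshape to `(2, C/2)`, transpose, flatten). The GSBottleneck is two
stacked GSConvs, `C -> C/2 -> C` with 3×3 kernels and an identity shortcut
when shapes match; the layout is channel-preserving, and its width ratio is
a free parameter held at 0.5. GSC2f is the C2f topology with GSBottlenecks
substituted for the standard bottlenecks. The toggle replaces the neck's
C2f blocks and also its two strided downsample convolutions (with GSConv),
the neck being the stated insertion region for the slim convolutions;
backbone C2f blocks stay standard.

**MECS.** The channel stage pools each channel globally by average, max and
median (even pixel counts take the mean of the two middle order statistics
— a convention this package fixes, since the operator is not otherwise
defined), pushes each pooled vector through one shared two-layer 1×1-conv
MLP with a ReLU between, applies a sigmoid per branch, and *sums the three
sigmoids*. The gate therefore lies strictly in (0, 3) rather than (0, 1);
the formula is implemented as printed in the block's description even
though the CBAM lineage sums before the squashing — the tests pin this
structural choice (a two-branch degradation is bounded in (0, 2)). The
spatial stage applies a 5×5 depthwise base conv, then separable strip
depthwise pairs (1×k then k×1) at several scales to the base output, sums
base and branches, projects with a 1×1 conv, and multiplies the result
into the channel-weighted features.

**BFM.** Two same-shape maps are each passed through shared multi-scale
convolutions (3×3, 5×5, 7×7, summed — sum rather than concat keeps the
width fixed). Channel descriptors concatenate global average, max,
standard-deviation (population convention) and minimum pooling and project
them through a shared bottlenecked 1×1-conv pair; spatial descriptors are
the channel-wise mean and max maps through one shared 7×7 conv. A two-way
softmax across the input axis — implemented exactly as the sigmoid of the
logit difference — guarantees the two channel weights sum to one per
channel and the two spatial weights sum to one per pixel. The fusion is
multiply-per-dimension then add: `y = ws1*wc1*t1 + ws2*wc2*t2`. Because
every weight path is shared between the inputs, fusing a map with itself
yields weights of exactly 0.5, a property the tests rely on. The block is
described in the change-detection literature as bitemporal; in this
single-image detector the two "time points" are re-read as the top-down
(upsampled deeper) feature and the lateral feature at each neck fusion
node, and BFM replaces the plain concatenation there.

## Pinned hyperparameters and the budget constraints

Several quantities are not stated anywhere in the family's description: the
MECS reduction ratio and insertion points, the exact strip-kernel set, the
BFM internal widths, and the GSBottleneck ratio. Following the reported
complexity budgets for the family (parameters in millions and GFLOPs at
640×640, both to one decimal), these were fixed once against the reported
MECS-variant total (3.3 M / 9.2) and the full-model total (4.1 M / 10.9):

* MECS: reduction ratio `r = 2`; strip kernels {7, 11, 21, 35, 41}; one
  block after each of the four backbone stage outputs (stride 4 to 32).
* BFM: fused width equal to the lateral input's channel count; multi-scale
  convs grouped at 8 channels per group; descriptor MLP hidden width
  `1.6 C`; top-down laterals (raw backbone features) pass through a 1×1
  projection, bottom-up laterals (neck outputs already at the fused width)
  enter directly.
* GSC2f: bottleneck ratio 0.5; neck downsample convs swapped to GSConv.

With these pins the package computes: baseline 3,013,757 parameters /
8.1 GFLOPs; MECS-only 3.3 M / 9.2; MECS+GSC2F 2.9 M / 8.3; full model
4.1 M / 10.9.

Two reported numbers cannot be reproduced, and the reason is structural
rather than a tuning failure. First, the reported baseline pair
(3.0 M, 8.6 GFLOPs) is internally inconsistent: a v8n-topology detector
with a 15-class head has 3.01 M parameters but about 8.1–8.2 GFLOPs under
the two-operations-per-multiply-accumulate convention; the 8.6–8.9 GFLOPs
figures circulating for this architecture belong to the 80-class head,
which would print 3.2 M parameters. No class count satisfies both printed
values. Second, the reported ablation table is not additive: the BFM-only
and MECS+GSC2F rows together with the baseline imply a full-model total of
9.8 GFLOPs / 3.9 M, while the full model is reported at 10.9 / 4.1. Any
implementation whose blocks behave identically regardless of which other
blocks are enabled — which is what an ablation study presupposes — can
therefore match at most a subset of the rows. This package pins the free
widths against the full model (the family's headline configuration, which
also fixes the MECS-variant row); the standalone BFM-only variant then
computes 4.2 M / 10.7 against the reported 4.0 / 10.1. The acceptance test
asserts the achieved values explicitly so any drift is caught.

## FLOP accounting conventions

The profiler costs a convolution as `2*H*W*(Cg*Kh*Kw + 1)*Cout` with `H, W`
the *output* map dimensions and `Cg` the per-filter (per-group) input
channel count, and a fully connected layer as `(2I − 1)O`. The formula's
source text reads "input feature map" for `H, W`, but applied literally to
strided convolutions that choice quadruples their cost and cannot land in
the reported magnitude; the output-dimension reading is the standard
MACs-times-two convention and is the one used throughout. Normalization
and activation layers are costed at zero; batch-norm scale and shift are
counted as trainable parameters. The per-layer breakdown is produced by
replaying the model's own `forward()` on a shape-only tensor, so the
report measures exactly the executed graph and totals equal the sum of the
breakdown by construction; parameters of weight-shared paths (MECS's MLP,
BFM's shared extractors) are costed once per pass, FLOPs once per
application.

`complexity_bounds()` reproduces the printed closed-form time complexities
of standard, depthwise-separable and GS convolution *verbatim*, including
two apparent typographical omissions (the kernel width missing from the
standard-conv product and the output channels missing from the GSConv
product). They are reproduced rather than corrected because they are
reported formulas; the profiler's numeric ordering DSC < GSConv < SC is
checked independently of them.

## Synthetic scenes

No deposited dataset accompanies the detector, so the generator emulates
the reported statistics of the field imagery: ~15 lesion classes with
imbalanced sampling weights (a linear ramp from 800 down to 300, matching
the reported most/least-represented class counts), a Poisson-distributed
lesion count with mean 2 (truncated at 8), bounding-box areas uniform on
[200, 8000] px² with a 5% tail up to twice the upper edge, leaf-textured
backgrounds with vein structure, soil/debris clutter patches, and a global
brightness factor in [0.65, 1.35]. Lesions are elliptical blobs with
low-order Fourier boundary perturbations and class-specific hue,
saturation, ring-versus-solid texture and spot frequency; boxes are
tightened to the drawn mask. Scenes are byte-deterministic given the seed.
Splits follow the 7:2:1 floor/floor/remainder rule, which reproduces the
reported 4088/1168/585 partition of 5841 images exactly.

What the generator does *not* emulate: real lesion morphology and
within-class variability, occlusion by other leaves, specular highlights,
camera noise, and inter-class visual similarity structure. Passing tests
on these scenes demonstrate that the pipeline (assignment, losses,
decoding, metrics) is wired correctly and can overfit a small sample; they
say nothing about detection accuracy on real plant imagery, which is why
no accuracy figure from the original study is asserted anywhere in the
package.

## Training and its numerical choices

The loss is the family-standard composition: binary cross-entropy on class
logits with soft targets, complete-IoU on decoded boxes, and a
distribution-focal term on the two integer bins bracketing each target
side distance, weighted 0.5 / 7.5 / 1.5 and normalized by the summed
target scores. Positive cells are chosen by task-aligned assignment:
candidates are cells whose center lies inside a ground-truth box, scored
by `score^0.5 * IoU^6`, top-10 per object, conflicts resolved to the
highest score, with target scores normalized per object to its peak IoU.
The assignment is computed on detached values; gradients flow through the
classification logits, the softmaxed side distributions and the decoded
boxes. The CIoU gradient is evaluated by central finite differences on the
(few) positive boxes per step — the loss is piecewise smooth and the
4-coordinate probe at `1e-3` px is well inside the smooth regime; all
other operators (convolutions, batch norm in training mode, softmax,
median pooling, the attention stages) carry exact hand-derived adjoints,
verified against finite differences in the test suite.

Defaults mirror the reported regime (300 epochs, batch 16, SGD, learning
rate 1e-4, 640 px, training from scratch). That learning rate is unusually
low for from-scratch training; it is kept as the documented default, and
the desk-scale smoke profile overrides it. The smoke profile used by the
tests — chosen as the smallest configuration that still exercises every
component — trains a width-0.125 model on eight 64×64 synthetic scenes
with two classes, batch 8, SGD momentum 0.9 at lr 0.01, for 200
iterations; it halves the initial loss within those iterations and lifts
train-set mAP50 from 0.0 to above 0.8. Batch-norm uses batch statistics
with biased variance in training, running statistics (momentum 0.03) at
inference.

Other conventions: precision is 1 when there are no predictions and recall
is 1 when there is no ground truth; classes without ground truth are
excluded from class means; average precision uses the precision envelope
with 101-point interpolation (an all-point variant is available), matching
the COCO-style language of the IoU-swept metric; matching is greedy in
descending confidence with ties broken by first occurrence; NMS is greedy,
per class, at IoU 0.45 with confidence threshold 0.25 by default; decoded
boxes are clipped to the image.

## Known limitations

The tensor engine is CPU-only, single-threaded R with C++ kernels; it is
sized for desk-scale experiments (tens of images, hundreds of iterations),
not for the full 300-epoch regime, although that regime is reachable
through the same configuration surface. The rotation augmentation uses
nearest-neighbour resampling and replaces rotated-out regions with black.
The confusion matrix matches class-agnostically (so cross-class confusion
is visible), which differs from the per-class matching used for AP.
Checkpoints serialize with R's native format and are not interchangeable
with other frameworks.
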