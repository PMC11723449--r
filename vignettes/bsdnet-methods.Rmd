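---
title: "Methods: the dual-branch feature mixer and prediction balance module"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dual-branch feature mixer and prediction balance module}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Detecting and identifying bird species in surveillance imagery is hard for
two structural reasons. First, species share local structure — beaks, wing
edges, body silhouettes look alike across species — so a detector built
purely from local convolutional features confuses similar classes. Second,
field data are long-tailed: a few common species dominate the annotated
pixels while rare species contribute almost none, and detectors overfit the
head classes. `bsdnet` implements a single-stage convolutional detector that
addresses both: a **dual-branch feature mixer** (DBFM) that fuses local
detail with gated global context in the backbone's downsampling stages, and
a **prediction balance module** (PBM) that counteracts class imbalance
purely at training time.

## Network architecture

The network follows the anchor-free single-stage template: a two-convolution
stem (each Conv–BN–SiLU, stride 2) brings the input to stride 4 at width
`C1`; three downsampling stages produce P3/P4/P5 at strides 8/16/32; an SPPF
block enlarges the receptive field at P5; a PAFPN neck (top-down + bottom-up
with C2F fusion) mixes the scales; and a decoupled head emits per-cell
classification logits and a distribution-focal box representation (16 bins
per box side) at each of the three scales. The *medium* scale uses depth
multiple 0.67, width multiple 0.75 and a 768-channel cap, giving backbone
level widths (48, 96, 192, 384, 576). With `use_dbfm = FALSE` the three
stages are plain strided Conv + C2F and the network is the conventional
medium-scale baseline: 25,972,104 parameters and 79.33 GFLOPs at 640×640
for 200 categories.

## The dual-branch feature mixer

Each DBFM stage transforms an input map `F` (C channels) into an output at
half resolution:

* **Local-detail branch.** A C2F stack on `F` (split, `n` residual
  bottlenecks, concatenation of all intermediates, 1×1 fuse) — the standard
  local feature extractor, `LD = C2F(F)`.
* **Global-information branch.** A gated pointwise/depthwise unit in the
  gMLP spirit:

  ```
  F1, F2 = Split(SiLU(BN(Conv1x1(F))))          # 1x1 expands C -> 2C
  GI     = Conv1x1( GELU(DWConv3x3(F1 + F)) * F2 ) + F
  ```

  The 1×1 expansion to 2C is what makes the arithmetic well-typed: both
  halves of the split then have C channels, so `F1 + F` and the final
  residual `+ F` are elementwise sums. The depthwise 3×3 extracts spatial
  structure cheaply; the GELU-gated product with `F2` modulates every
  channel-position by learned context; the final 1×1 mixes channels. With
  the final convolution zeroed the branch is exactly the identity — a
  contract the tests assert bitwise.
* **Fusion.** `Fd = SiLU(BN(Conv1x1(Concat(LD, GI))))`, LD first. The fused
  width follows a per-stage schedule (below).
* **Space-to-depth downsampling.** Instead of a stride-2 convolution, `Fd`
  is rearranged into its four even/odd sub-grids at offsets (0,0), (1,0),
  (0,1), (1,1), stacked along channels (a lossless bijection,
  `4c × h/2 × w/2`), and mixed by a final 1×1 convolution. Small-kernel
  mixing after a lossless rearrangement preserves fine, small-object detail
  that strided 3×3 sampling discards.

**Design choices made where the design was open.** (1) The fusion output is
*not* added back onto the input map: the fused width differs from the input
width in two of the three stages, and the global branch already carries its
own residual, so a second outer residual would add a constraint without a
clear benefit. (2) The local branch consumes `F` directly rather than a
projected copy. (3) GELU uses the exact erf formulation (`x·Φ(x)`), since
the tanh approximation differs at the 1e-3 level and would blur the
hand-computed oracles in the test suite.

**Width schedule.** The mixer's internal widths are fixed constants of the
architecture, chosen once so that the three stages of the medium model add
+4.7 M parameters and +17 GFLOPs over the baseline stages they replace —
the published budget of the module. Per stage (input widths 96/192/384 at
medium): local C2F widths (32, 96, 512), bottleneck repeats (1, 2, 7),
fused widths (96, 96, 1536). The early, high-resolution stages stay lean
(every parameter there costs ~4× the FLOPs of a stage-3 parameter); the
deepest stage carries the bulk of the capacity, which is also where global
context is most semantically meaningful. At other scales the schedule is
expressed as fractions of the stage input width with repeats scaled by the
depth multiple. Result: 30,647,592 parameters and 96.35 GFLOPs for the full
medium model at 200 categories.

**A note on "global".** The branch's spatial footprint per layer is 3×3;
its context aggregation comes from channel gating and, during training,
from batch normalization statistics that couple every position. The test
suite probes exactly that: in training mode a single-pixel perturbation
measurably shifts the branch output far outside the local footprint.

## The prediction balance module

PBM measures, once before training and at original image resolution, the
total annotated box area `p_k` of every category and forms the inverse
class frequency

```
Pix_k = log( sum_i p_i / p_k ),
```

so the head category has `Pix` near 0 and rare categories large `Pix`.
Each training iteration draws one fresh Gaussian per category,
`delta_k ~ N(0, sigma^2)`, and perturbs the classification logits of every
prediction location by

```
Variation_k = Pix_k / max_i Pix_i * delta_k .
```

The head class is barely perturbed; tail classes receive noise at the full
scale `sigma`. The perturbation exists only inside the training loss — at
inference the scores are untouched (asserted bitwise), so PBM adds zero
parameters, zero FLOPs and zero deployment cost.

Three readings were open and are resolved as follows. *Sigma semantics*:
`sigma` is the standard deviation of the base draw (`N(0, sigma^2)`); the
reference configuration scans sigma over 3–6 as a scale knob and settles on
4, which is the package default. *Perturbation target*: the raw
classification logits before the BCE loss, not post-sigmoid probabilities —
this keeps the loss well-defined at any noise scale. *Sampling frequency*:
one variation vector per batch, shared across locations; per-anchor
resampling would be a noisier, more expensive variant. Categories with no
annotated pixels are clamped to `p_k = 1` with a warning rather than
failing.

## Training recipe

SGD with initial learning rate 0.01 and momentum 0.937, batch 16, 100
epochs from scratch (no pretrained weights), weight decay 5e-4 on
convolution weights only, 3 warmup epochs then cosine decay to 1% of the
initial rate. Augmentation is mosaic (2×2 composite around a random
center, boxes clipped, sub-pixel remnants dropped) followed by random zoom
(0.5–1.5) and translation (±10%), with mosaic disabled for the last ten
epochs; magnitudes are the detector family's conventional defaults since
only the augmentation types are prescribed. The loss combines BCE
classification (weight 0.5), CIoU (7.5) and distribution-focal regression
(1.5). Assignment is deterministic and center-based: each ground truth goes
to the scale whose stride best matches its size (largest side ≈ four
cells) and to the cell containing its center; conflicts resolve to the
larger box, making assignment invariant to annotation order. Validation
during training is PBM-free, as is any inference.

The engine differentiates the network on a reverse-mode tape
(im2col/GEMM convolution kernels in C++); the loss gradients (softmax-
expectation chain for the focal bins, piecewise-linear CIoU geometry with
the aspect weight held constant, the usual convention) are closed-form and
verified against finite differences in the test suite.

## Metrics

Average precision is the literal rank summation `AP = Σ (R_n − R_{n−1}) P_n`
over detections in descending confidence, with `R_0 = 0` and no
interpolation; a 101-point interpolated variant exists behind a flag for
cross-checking only. Matching is greedy one-to-one by confidence with
highest-IoU tie-break (ties to the lower ground-truth index). mAP averages
per-category AP, excluding categories absent from the ground truth;
`mAP50:95` averages the 0.50:0.05:0.95 threshold ladder. Scalar precision
and recall are reported at the F1-optimal confidence, labeled with that
threshold, since the operating point of published tables is not otherwise
specified. A report with no ground truth at all flags mAP as undefined
rather than silently returning zero.

Profile tables report millions of parameters and GFLOPs truncated (not
rounded) to one decimal — the convention under which the published
medium-baseline row (25.97 M → 25.9) is reproduced — and FLOPs count one
multiply–accumulate as two operations over convolutions and linear maps
at batch 1, with pooling, activations, upsampling and the space-to-depth
rearrangement free.

## The synthetic scene generator

Real bird-surveillance data cannot ship with a package, so the generator
produces the two properties the method targets, controllably: category `k`
is drawn with probability ∝ `(k+1)^−a` (long tail), and every sprite shares
a body-plus-beak motif with a category-colored wing patch whose salience
shrinks as `motif_overlap → 1` (local structural similarity). Backgrounds
are low-frequency noise so objects are not trivially separable. The
generator writes exact per-category pixel-sum ledgers that the PBM
statistics must reproduce to integer equality, and is byte-reproducible
from its seed. Defaults (8 categories, 128×128 scenes, exponent 1.5,
1–4 objects of 16–48 px, overlap 0.5) describe a desk-scale long-tailed
multi-object regime.

What it does *not* emulate: photographic texture, pose articulation,
occlusion, motion blur, scale imbalance between images, or label noise.
Tests passing on these scenes demonstrate the machinery (shapes, gradients,
schedules, metrics, statistical contracts) — not field accuracy on real
imagery, which requires GPU-scale training on real datasets and is out of
scope here.

## Problem sizes used by the tests

The suite exercises the full medium model only through the analytic
profiler (building it takes seconds; no forward pass at 640×640 is
needed). Forward/backward paths run on a reduced-width configuration
(width multiple 0.125, depth 0.33) at 64×64 input: the end-to-end smoke
trains it for 200 iterations on eight synthetic scenes and requires the
training loss to more than halve, which it does with a wide margin
(typical final/initial ratio ≈ 0.12). Monte-Carlo contracts use 1e5 draws
(PBM scale, 2% tolerance) and 200 random scenes (metric equivalence to an
independent brute-force evaluator at 1e-9).

## Known limitations

* The engine is CPU-only and single-threaded; it is built for correctness,
  contracts and desk-scale experiments, not for training on real datasets.
* Target assignment is the simple deterministic center-based rule, not a
  task-aligned dynamic assigner; on dense scenes with heavily overlapping
  same-scale objects some ground truths can share a best cell and the
  smaller one is then unassigned for that iteration.
* Checkpoints store plain R arrays; there is no export path to deployment
  formats.
* The 101-point AP variant is provided for comparison only; all reported
  numbers use the rank-summation definition.
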