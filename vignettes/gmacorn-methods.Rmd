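---
title: "Methods: lightweight whorl detection and delivery timing in gmacorn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lightweight whorl detection and delivery timing in gmacorn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Blanket spraying wastes pesticide; for corn at the V6-V8 stage the
granules only need to reach the whorl — the funnel of young leaves at the
top of each plant, which channels granules to the growing point. A
vision-guided applicator therefore needs four cooperating pieces: a
detector that finds whorls in overhead imagery on an embedded device, a
decision rule that converts detections into actuation signals, a timing
model that accounts for the camera sitting ahead of the release funnel,
and metrics that quantify the whole chain in the field. `gmacorn`
implements all four, plus a procedural scene generator so that every
stage can be exercised and tested without field data.

## Numerical engine

No deep-learning framework is assumed. Feature maps are R arrays with
dim `(H, W, C, N)`; dense convolution is im2col (compiled) followed by a
BLAS GEMM, while depthwise convolution, max/average pooling and
nearest-neighbour resampling run as compiled loops. Every layer carries a
hand-written backward pass; all of them are validated against central
finite differences in the unit tests (agreement ~1e-9). Batch
normalisation uses batch statistics during training (eps 1e-3, running
momentum 0.03) and running statistics in evaluation.

## Detector family

The baseline is the standard nano-scale single-stage graph: a stride-2
stem, four C2f stages, SPPF, an FPN+PAN neck and an anchor-free decoupled
head predicting, per scale (strides 8/16/32), a 16-bin discrete
distribution for each of the four box-side distances plus class logits.
Configured for one class, its deploy-mode footprint is 3.0 M parameters
and 8.1 GFLOPs at 640 x 640 — the reference figures for this model family
— which pins down two conventions used throughout the package:

- **Deploy-mode parameters** are counted with every batch-norm folded
  into its convolution (the conv keeps a bias) and without the auxiliary
  head. The 16 fixed distribution-projection weights are not learnable
  and are excluded.
- **FLOPs** are 2 x multiply-accumulates over convolution layers only, at
  batch 1; biases, normalisation, activations, pooling and resampling are
  free. Under these conventions the full-size forward pass is also
  executable numerically, and profiling is analytic (shape inference), so
  it is exact and instantaneous at any resolution.

The lightweight variant replaces the backbone with a hierarchical
("HG") design: a two-convolution stem, then four blocks in which `n = 3`
successive GhostConvs are concatenated with the block input and fused by
1x1 squeeze/excite convolutions, with depthwise stride-2 convolutions
between stages. Every GhostConv produces half its channels densely and
the other half as 5x5 depthwise transforms of the primary output (ratio
s = 2; the cheap branch carries BN but no activation). SimAM sits after
SPPF at the P5 position; the neck C2f blocks become CM blocks, i.e. each
bottleneck ends in an MLCA gate; an auxiliary detection head on the same
three neck scales exists only in the training graph.

The stage widths are not dictated by the architecture description, so
they are treated as the free calibration of the family: stem 16,
per-stage GhostConv widths (24, 48, 56, 112) and stage outputs
(48, 64, 128, 256) were fixed once so that the deploy footprint lands on
the published complexity of this design point — 2.3 M parameters and
6.8 GFLOPs at 640 — and are not revisited. The resulting raw parameter
reduction against the baseline is 23.4% (the printed 23.3% is the
rounded-table derivation 0.7/3.0).

## Attention operators

**SimAM** assigns neuron `t` the closed-form minimal energy
`e* = 4 (sigma^2 + lambda) / ((t - mu)^2 + 2 sigma^2 + 2 lambda)` and the
weight `sigmoid(1/e*)`. The implementation uses exact leave-one-out
channel statistics (for each neuron, `mu` and `sigma^2` over the other
`M - 1` spatial positions, variance with denominator `M - 1`), which makes
the operator agree with direct numerical minimisation of the underlying
binary-label energy even on two-neuron channels; on realistic map sizes
it coincides with the usual shared-statistics approximation. `lambda`
defaults to `1e-4`, the value conventional for this operator (the source
description leaves it unstated). Single-pixel channels have degenerate
statistics and are passed through unchanged with a warning. In the
training graph the gate is treated as a constant during backpropagation
(stop-gradient on the attention map): the operator has no parameters of
its own, and the identity path carries the exact gradient for everything
upstream.

**MLCA** is described by its branches only, so the package fixes a
concrete instantiation: average-pool to a g x g grid (g = 5) and run a
1-D convolution across channels at every cell (local branch); globally
average-pool and run a second 1-D convolution (global branch); average
the two, squash with a sigmoid and resample to the input resolution as a
multiplicative gate. Kernel lengths follow the efficient-channel-attention
rule (nearest odd to `(log2(C) + 1)/2`), so the whole gate owns two
1-D kernels — single-digit parameter counts per block. Inside the
network the grid is clamped to the map size so that deep scales of small
training images remain valid; the standalone operator keeps the strict
error. Its backward pass is exact.

**GhostConv** calculators implement the compression/speed-up ratio
`R_C = s c k^2 / (c k^2 + (s - 1) d^2)`, the formulation that reproduces
both the direct kernel-count ratio (e.g. 36864/18720 at c = n = 64,
k = d = 3, s = 2) and the `-> s` limit; the printed form of these ratios
in the source text is typographically garbled and was corrected to this
standard formulation.

## Label assignment and loss

The source description cites both a coarse-to-fine auxiliary-head scheme
and SimOTA without reconciling them. The package implements the lead
head with a task-aligned assigner (candidates are anchors whose centre
lies inside the ground-truth box, ranked by `score^0.5 * IoU^6`, top-10
kept, conflicts resolved by the larger metric; soft targets are the
metric normalised per ground truth to its best IoU). The auxiliary head
relaxes this — candidate window doubled about the box centre, top-k
doubled — and its positives are defined as the union with the lead
positives, which makes the superset property structural rather than
statistical. SimOTA (dynamic k = clamped rounded sum of top-q IoUs,
lowest-cost selection, cheapest-match conflict resolution) is available
as an explicit-cost-matrix assigner.

The loss is binary cross-entropy on the soft class targets, a
complete-IoU box term and a distribution-focal term (gains 7.5 / 0.5 /
1.5; auxiliary loss weighted 0.25, the usual convention for deep
supervision). Two numerical choices: the distribution decode is
differentiated analytically through the softmax expectation, while the
complete-IoU term is differentiated by central finite differences over
the four box coordinates of the positive anchors (step 1e-3 px; a few
dozen extra vectorised IoU evaluations per step). Training uses SGD with
lr 0.01, momentum 0.937 and weight decay 5e-4 under a linear schedule.

The smoke loop is exactly that — a demonstration of end-to-end
trainability at desk scale (tens of steps on tens of low-resolution
synthetic scenes), not a path to field accuracy. Because the task-aligned
targets move with the predictions, per-step loss traces plateau with
jitter; the tested property is the decreasing trend (final below initial,
second-half mean below first-half mean), which holds across seeds.

## Decision engine and timing model

The trigger test is centre-point containment with inclusive edges: the
decision algorithm hands only the detection centre to the region test,
so that is the precise contract (the surrounding prose says "overlaps").
Debounce is not part of the source algorithm and is added as an
engineering necessity: a refractory window (default 15 frames, about
0.5 s at 30 fps) plus a region occupancy flag prevent re-triggering on
the same plant while letting consecutive plants trigger independently.
Packets are ASCII `"X<x>,Y<y>,C<round(100 conf)>\n"` and round-trip
through the parser losslessly; serial transmission is abstracted behind
a byte sink.

The timing chain models the camera mounted a distance L1 ahead of the
funnel: detection happens at the camera crossing, release after
`T1 + T4`, and the granules fall `T2 = sqrt(2 (H1 - H2)/g)` with no
horizontal velocity relative to the platform (drag and wind omitted —
solid granules are barely wind-affected). Exact delivery requires
`T1 + T2 + T4 = T3 = L1/V1`; `required_delay()` solves for T4 and raises
when the platform is too fast. The simulator perturbs this chain with
per-plant speed variation (optionally compensated by re-solving T4 from a
noisy speed estimate), release-timing jitter and trigger-position error;
under zero noise the landing offset is identically zero. The study never
prints the L1/H1/H2/V1 actually used (only "camera about 0.5 m above the
plants"), so scenario defaults are illustrative, not calibrated.

## Metrics conventions

AP uses greedy confidence-ordered matching (ties broken by detection
index, each ground truth matched once, IoU threshold 0.5) and the
all-point interpolated integral of the precision-recall curve; it is
cross-checked against an independent threshold-enumeration oracle to
1e-9. The field triple is delivery rate `N_success/N_total`, detection
accuracy `N_identified/N_total` (the field instantiation of the
correct-over-total-leaf-areas ratio) and delivery precision
`N_success/N_identified`; the identity rate = accuracy x precision / 100
holds exactly before rounding. Percentages are rounded half-up to one
decimal as tabulated in field reports. Group summaries are the mean and
sample (n-1) standard deviation of the tabulated one-decimal group
values: that is the convention under which a published group table and
its mean +/- SD row are mutually consistent (computing from unrounded
ratios shifts the delivery-precision mean from 92.2 to 92.1, and a
population SD gives 3.1/1.8/2.7 instead of 3.3/1.9/2.9).

## Synthetic scenes

The generator renders flat-shaded procedural geometry: a smoothed-noise
soil background, radially arranged elliptical leaves and a bright
central whorl per plant, one whorl-covering box per plant in YOLO
normalised format, deterministic per seed. Augmentations mirror the
dataset-expansion recipe: brightness within +/-25%, rotation about the
image centre (boxes become clipped axis-aligned hulls of their rotated
corners; boxes leaving the frame are dropped with a log message) and
directional motion blur. The expansion factor of the source datasets is
not uniquely determined (162 -> 1085 and 800 -> 2400 imply different
factors), so multiplicity is a parameter. Detection streams move plants
across the frame at constant speed with optional jitter and dropouts at
a nominal 30 fps.

What the generator does *not* emulate: real leaf texture and occlusion,
lighting extremes, camera distortion, and the appearance diversity that
drives field detection accuracy. Passing pipeline tests on these scenes
demonstrates the correctness of the plumbing — assignment, loss,
decision logic, timing — not the field performance of a trained model;
the published detection mAPs require the original field datasets and
full-scale training, which are outside this package's reach.

## Problem sizes used by the test-suite

Unit tests use a width-reduced detector variant (stem 8, stage outputs
16/16/32/64, one GhostConv per block) on 96 px scenes; the acceptance
checks build the full-size variants for profiling (analytic, seconds)
and run the 50-step smoke training on sixteen 160 px scenes with batch
2. These sizes were chosen as the smallest that exercise every code path
meaningfully.

## Known limitations

- The engine is CPU-only and double-precision; it is built for
  correctness and desk-scale training, not throughput.
- Deploy-mode complexity matching is the calibration target for the
  lightweight backbone; other width choices reproduce the same footprint
  and would behave equivalently here.
- The SimAM gate is non-differentiated by design; MLCA kernels do train.
- The delivery simulator is one-dimensional along the row; terrain,
  multi-row cascade scheduling and granule-leaf rolling dynamics are out
  of scope.
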