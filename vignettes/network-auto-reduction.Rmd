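---
title: "Compound network reduction for histopathology patch classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound network reduction for histopathology patch classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narcnn)
```

## The problem

Whole-slide images are gigapixel rasters: a single slide partitions into
tens of thousands of 50 × 50 µm patches, and mapping tumor-infiltrating
lymphocytes (TILs) across a cohort means running a CNN classifier on every
patch of every slide. Inference cost, not model accuracy, is the binding
constraint. `narcnn` implements *network auto-reduction* (NAR): instead of
pruning individual filters, it shrinks a trusted architecture's three
capacity dimensions — depth (block repeats), width (channel counts) and
input resolution — *together*, by coupled coefficients, so the reduced
network stays internally balanced.

## The reduction model

A block-based CNN is a stem, a sequence of stages (a block template
repeated $L_i$ times at base width $C_i$), and a head, applied to an
$H \times W$ input. Given bases $\alpha, \beta, \gamma > 1$ and a single
exponent $\varphi \ge 0$, the reduction factors are

$$d = \alpha^{-\varphi}, \qquad w = \beta^{-\varphi}, \qquad
  r = \gamma^{-\varphi},$$

and the reduced network has $\mathrm{round}(d\,L_i)$ repeats,
$\mathrm{round}(w\,C_i)$ base widths (per-layer ratios such as the 1:1:4
bottleneck expansion are preserved exactly), and a
$\mathrm{round}(r\,H) \times \mathrm{round}(r\,W)$ input. Convolution cost
is proportional to depth, to the product of input and output channels, and
to spatial area, so the total FLOPs scale as $d\,w^2 r^2$ before rounding.
Balanced coefficients keep $\alpha \beta^2 \gamma^2 \approx 2$, giving a
theoretical cost ratio of $2^{-\varphi}$: one unit of $\varphi$ halves the
inference cost. The defaults $\alpha = 1.2$, $\beta = 1.1$,
$\gamma = 1.15$ (their constraint product is 1.9203, checked with a ±0.1
tolerance by `check_constraint()`) are the grid-searched values reported
for the TIL task; searching them anew is out of scope here, they are
configuration.

The package also implements the *input-reduction* (IR) baseline —
`input_reduce()` scales only the image and leaves the architecture
untouched — which is the natural control for whether balanced compound
reduction is actually needed.

### Numerical choices

* **Rounding** is nearest-integer with ties-to-even, with values within
  $10^{-9}$ of an exact half snapped to the half first (products like
  $3 \times 1.2^{-1}$ sit a few ulps off 2.5 in floating point). This rule
  reproduces every unambiguous cell of the published reduced-architecture
  tables for this family — `3 × 1.2⁻¹ = 2.5 → 2` together with
  `232.73 → 233`, `105.79 → 106`, `157.8 → 158` force nearest/ties-to-even
  over half-up.
* Repeats and widths are clamped at 1; the reduced input side is clamped
  at the template's minimum (32 for the bottleneck template, 96 for the
  Inception stem).
* Depth scaling applies only to stages flagged `depth_scalable`; stems,
  downsampling transitions and heads are never removed, so every reduced
  network keeps the original's downsampling structure.
* $\varphi$ may be any non-negative real; the published configurations use
  integers 1–6, and above 3 the bottleneck template degenerates toward
  single-repeat stages (the transform warns).

## Architecture representation and the two templates

Networks are held in a symbolic intermediate representation
(`network_spec()`): widths inside a block are rational multiples of the
stage base width, so the same description serves the original and every
reduced variant, and `network_to_json()` / `network_from_json()` round-trip
it losslessly. A single compiler expands the symbolic form into a flat
layer graph used by shape inference, the cost model and the runtime, so
instantiation rules live in one place.

`resnet50v2_template()` is the pre-activation bottleneck network: 7×7/64
stride-2 stem convolution plus 3×3/2 max pool; stages of base widths
64/128/256/512 with repeats 3/4/6/3 and 1:1:4 bottleneck ratios;
batch-norm and activation precede each convolution. Two conventions were
genuinely open and were calibrated against the published figures for this
configuration, then frozen:

* **Bias placement.** Stem convolution, the final 1×1 convolution of each
  block, projection shortcuts and the dense head carry biases; the first
  two convolutions of a block do not. With batch-norm counted at 4
  parameters per channel (scale, shift, and both moving statistics), the
  2-class network totals exactly 23,568,898 parameters.
* **Stride placement.** Downsampling happens at the *start* of stages 2–4,
  on the 3×3 convolution and the projection shortcut. This is the original
  pre-activation convention; it reproduces the published 9.65 GFLOPs at
  240 × 240 within 0.5% and the whole input-reduction cost series within
  2%, whereas the end-of-stage variant used by one popular framework port
  computes 8.24 GFLOPs and is inconsistent with those figures.

`inception_v4_template()` is the canonical Inception V4 topology
(valid-padding stem with three branched mixing blocks, then 4 × A,
Reduction-A, 7 × B, Reduction-B, 3 × C). The A/B/C groups are
depth-scalable stages; the reduction blocks are transitions tied to each
stage's base width. At its native 299 input the cost model yields
2 × 12.25 G multiply-accumulates, matching the architecture's published
cost, which pins the topology down.

## Cost model

`cost_report()` infers every layer's output shape (`same` padding:
⌈side/stride⌉, required for the non-multiple-of-32 reduced inputs such as
209 or 181; `valid`: ⌊(side − k)/stride⌋ + 1) and counts

$$F_{conv} = 2\, C_{in} K_h K_w H_{out} W_{out} C_{out}, \qquad
  F_{dense} = 2\, n_{in} n_{out},$$

i.e. two operations per multiply-accumulate over convolutional and dense
layers only. Batch-norm, pooling, activations and shortcut additions cost
zero, and there is no bias-add term — the counting convention names only
those two layer kinds. Giga means $10^9$, reported half-up to two
decimals. Parameter counting includes batch-norm moving statistics; that
convention is what reconciles the 23,568,898 total above.

One published figure resists this (or, as far as we can determine, any)
convention: the 15.48 GFLOPs quoted for Inception V4 at 240 × 240. The
canonical topology computes 14.51 here. The quoted cost series for that
network is internally inconsistent — its step from 240 to 209 input is a
1.58× drop, more than the maximum any fixed topology can produce from area
scaling plus grid discreteness (≈1.44) — while the corresponding
bottleneck-network series is fully consistent with this cost model. The
package reports what it computes; the discrepancy is documented rather
than fitted.

## Runtime

`materialize()` allocates every parameter tensor for a compiled graph
(He-normal initialisation) and `train()` runs minibatch softmax
cross-entropy with Adam. The runtime is plain R over BLAS matrix products
(one product per kernel tap), which keeps it dependency-free, exactly
seed-reproducible across platforms, and honest about its scope: the full
templates materialize — the analytic and materialized parameter counts
agree exactly for both templates and all reduced variants, which is a
tested contract — but training is intended for small networks such as
`toy_cnn_template()`.

Protocol defaults follow the published training setup: learning rate
0.0005, weight decay 0.0005, 50 epochs, Adam. "Weight decay with Adam" is
ambiguous about coupling; it is implemented as *decoupled* (AdamW-style)
decay on convolution and dense kernels only, which is the better-behaved
modern reading. Batch size is unstated in the protocol; 32 is the default.
Evaluation uses the Mann–Whitney rank formulation of ROC AUC, averaged
over 3 seeded runs, cross-checked in the tests against an independent ROC
implementation.

## Slide pipeline and synthetic fixtures

`patch_grid()` tiles a slide into non-overlapping patches of fixed
physical size (50 µm, so 200 px at 0.25 µm/px or 100 px at 0.5 µm/px);
grids depend only on physical dimensions, trailing partial patches are
dropped, and coordinates are 0-based half-open boxes in row-major order —
conventions chosen here, since none are standard. `classify_patches()`
resizes each patch bilinearly to the classifier's input side, so the
per-slide workload is identical whatever input size a reduced model
expects. `build_til_map()` thresholds scores (default 0.5, configurable)
into a positive/negative grid, written as CSV and rendered red-on-blue as
PNG.

The synthetic generator stands in for the real stained-tissue patches,
which cannot ship with a package: `make_patch()` draws dark-purple
elliptical blobs (placed with a minimum-distance rule so they stay
distinct) on mottled pink texture — at least 20 blobs for a positive
patch, at most 2 for a negative one — and `make_slide()` /
`make_manifest()` assemble labelled slides and patch sets. The class
signal is blob *density*, not a global colour shift alone, so shrinking
the input resolution degrades the task gradually, which is what makes the
input-reduction sweep in the test suite meaningful. Everything is
deterministic per seed.

What the synthetic task does *not* emulate: stain variability, tissue
architecture, annotation noise, or the difficulty of real H&E patches.
Passing the end-to-end tests shows the pipeline is wired correctly and the
runtime optimises, not that a reduced network reaches any particular AUC
on real slides — the published accuracy numbers require the original
whole-slide cohorts and GPU-scale training and are deliberately out of
scope.

## Problem sizes in the test suite

The suite trains `toy_cnn_template(32)` (three conv/batch-norm/relu
stages, ~6k parameters) on 200 synthetic 64-px patches, evaluates on 100
held-out patches, for 5 epochs and 3 seeds; this finishes in well under a
minute on one CPU and reaches AUC ≈ 1, comfortably clearing the ≥ 0.9
acceptance bar. The input-reduction sweep retrains at input sides 32, 24
and 18 ($\varphi$ = 0, 2, 4) and asserts the held-out AUC is
non-increasing within a 0.05 noise band; on this easily separable task the
trend is typically flat rather than falling, so the assertion verifies
graceful degradation, not a particular decay rate. The full published
configuration (a $\varphi = 3$ reduced bottleneck network at 158 × 158) is
covered by the materialization and cost contracts instead of training: on
a CPU-only pure-R runtime that training run would take hours and would
demonstrate nothing the toy configuration does not.

## Known limitations

* FLOPs are analytic operation counts, not wall-clock or memory
  predictions; activation memory is not modelled.
* The runtime is deliberately desk-scale; it is not a substitute for a
  GPU framework when real training is the goal.
* Scaling *up* ($\varphi < 0$), coefficient search, pyramidal slide-format
  decoding and the pathologist annotation loop are out of scope.
* Average pooling divides by the full window size including padding, a
  simplification that only affects `same`-padded pooling at borders.
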