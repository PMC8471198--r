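---
title: "Grading knee osteoarthritis from radiographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading knee osteoarthritis from radiographs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Knee osteoarthritis (KOA) is graded radiographically on the
Kellgren–Lawrence (KL) scale: `Healthy` (no disease) and `GradeI`
(doubtful) through `GradeIV` (severe). The dominant imaging sign is
narrowing of the joint-space width (JSW) — the dark gap between the bright,
radio-opaque femur and tibia on a frontal radiograph — accompanied at higher
grades by osteophytes (bony outgrowths at the joint margins) and subchondral
sclerosis (locally denser, brighter bone next to the joint surface).

`koagrader` implements a hybrid grading pipeline over such radiographs:

1. **Preprocessing** — format normalization, optional photographic negative,
   bilinear downscaling.
2. **ROI localization** — a sliding-window search for the tibiofemoral joint
   scored by the mean absolute difference (MAD) between HOG descriptors of
   the window and of a template bank.
3. **Segmentation** — a two-phase piecewise-constant active contour that
   separates bone from gap inside the ROI.
4. **Descriptors** — histogram of oriented gradients (HOG), local binary
   patterns (LBP), and the global-average-pooled activations of a small
   convolutional network (CNN), plus concatenation-fused combinations.
5. **Classification** — linear SVM, k-nearest neighbours, or random forest
   over any descriptor kind.
6. **Evaluation** — binary (diseased/healthy) and five-class confusion
   matrices, percentage-split validation, and the report metric arithmetic
   reproduced verbatim (see below).

## The synthetic radiograph generator

Real graded radiographs are large, access-controlled, and unnecessary for
testing the pipeline's mechanics, so the package ships a seeded generator
(`synth_config()`, `generate_dataset()`) that emulates the features the
pipeline exploits:

* a knee silhouette: a bright bone column band (default 120 px wide) flanked
  by dark soft-tissue/air margins — this finite silhouette is what anchors
  template matching horizontally;
* two bone bands separated by a horizontal dark gap whose width is drawn
  from a per-grade integer range, by default `Healthy` 16–20 px, `GradeI`
  12–15, `GradeII` 8–11, `GradeIII` 4–7, `GradeIV` 1–3 — disjoint, strictly
  decreasing, and adjacent, so that neighbouring grades are genuinely
  confusable; the ranges are free parameters of the phantom, not
  radiological measurements;
* osteophytes as truncated Gaussian bright blobs at the four lateral gap
  margins, with per-grade probabilities 0/0.2/0.5/0.8/0.95, and a +20
  intensity sclerosis band hugging the gap for Grades III–IV — these give
  the texture descriptors signal beyond pure gap width;
* additive Gaussian noise (default sigma 8 on the 0–255 scale) clipped to
  the 8-bit range.

Defaults are 200×200 px, bone intensity 200, gap intensity 40, background
15. Every image records its ground truth (`true_roi`, `true_jsw`), and all
randomness flows through one stream seeded by `config$seed`, so datasets are
bit-reproducible. The vertical position of the joint and the horizontal
position of the silhouette are jittered per image.

What the phantom does *not* model: anatomical bone shapes, cortical/
trabecular texture, beam-hardening and exposure variation, lateral views,
bilateral knees, and patient positioning error. Passing tests on this
phantom therefore demonstrate that the pipeline's mechanics are correct and
that it recovers grade structure when the KL signs are present — not that it
reaches any particular accuracy on clinical data.

## ROI matching

Window and template are described by HOG vectors computed with identical
parameters, and scored by the mean absolute difference
`U = (1/h) * sum |v_win - v_tmpl|`; the window with the minimum score over
all stride-1 placements and all bank templates wins, with ties broken to the
smallest row-major position, then the smallest template index. MAD is a
pseudometric, so an exact copy of a template scores 0 and is recovered at
its exact position in the noiseless case. Because HOG is built from
gradients, matching is invariant to global additive intensity shifts.

The implementation is compiled (Rcpp): per-window bilinear resampling reads
the source image in place through precomputed interpolation tables, and the
MAD accumulation aborts once it exceeds the current best — both exact
optimizations that change nothing about the result.

## Segmentation

`segment_roi()` evolves a two-phase piecewise-constant (Chan–Vese-style)
segmentation: each sweep reassigns every pixel to the phase with the nearer
current mean (ties keep the previous label), then applies a 3×3
morphological despeckle that flips only pixels with no same-label neighbour.
A majority vote was rejected here because it erases one-pixel-thin
structures — exactly the near-obliterated joint gap of the severest grade.
The default initialization thresholds at the intensity midpoint
`(min+max)/2`; a geometric border-inset start can converge to a spurious
local optimum that separates sclerotic from plain bone instead of bone from
gap. Iteration stops when the changed-label fraction drops below `tol`
(default 1e-4, `max_iter` 200). The mask is oriented so 1 = bone (the
brighter phase; pass `bone = "dark"` for negative-preprocessed crops), the
update is complement-symmetric under intensity inversion, and a constant
input returns a flagged degenerate mask.

## Descriptors

**HOG.** The input is resized to 28×28 and divided into 4×4-px cells;
centred-difference gradients (one-sided at borders) vote into 9 unsigned
orientation bins over [0°, 180°) — opposite gradient directions share a bin
— with magnitude-weighted linear interpolation between neighbouring bin
centres (wrap-around). Blocks of 2×2 cells advance by 4 px (one cell) and
are L2-normalized (eps 1e-12). This is the unique geometry consistent with
a 1296-length descriptor on a 28×28 image: 6×6 block positions × 4 cells ×
9 bins. The cell size is not stated anywhere explicitly; 4×4 is forced by
the other constraints.

**LBP.** Each interior pixel is compared against its `k` ring neighbours
(`k` = 4, 8, or 16; radius 1, 1, 2 — integer Chebyshev rings, enumerated
clockwise from the top-left corner); neighbour `i` sets bit `2^i` when its
intensity is ≥ the centre (equality counts as 1, so a constant image codes
`2^k - 1` everywhere). The feature is the normalized 2^k-bin code
histogram, invariant under any strictly increasing intensity transform.

**CNN.** The feature network is `conv(20 filters, 5×5)` → `maxpool 2×2` →
`conv(32, 4×4)` → `maxpool 2×2` → ReLU → `conv(40, 4×4×32)` → global
average pool → dense softmax over the five grades, on 50×50 inputs scaled
to [0,1]; the CNN *feature* is the 40-long global-average-pooled last-conv
activation, and the softmax head exists only to train the weights. The
published description of this architecture is internally inconsistent (its
stated sizes cannot all hold at once, and a "1×1×2" final map is
unreachable with five classes); the resolution adopted here reads "filter
size of 20" as 20 filters of spatial size 5×5 and pool stride as 2, which
makes the map sizes 46×46×20 → 23×23×20 → 20×20×32 → 10×10×32 → 7×7×40.
Training is mini-batch SGD (batch 16, learning rate 0.01, momentum 0.9)
with He initialization and softmax cross-entropy, implemented natively via
im2col and BLAS matrix products; initialization and the per-epoch shuffle
derive from `spec$seed`, so training is bit-reproducible.

**Fusion.** Fused kinds (`HOG+CNN`, `LBP+CNN`, `HOG+LBP+CNN`) are plain
concatenations, CNN block first.

## Classification

Defaults, where the method itself leaves them open: SVM linear kernel with
`C = 1` and one-vs-one multiclass (via `e1071`); KNN with `k = 1` and
Euclidean distance, evaluated in-package so that distance ties resolve to
the smallest training index and voting ties to the smallest class index —
fully deterministic; random forest with 100 trees and the usual
sqrt-features split sampling (via `randomForest`, seeded).

Features are z-score standardized per dimension (statistics fitted on the
training split only) before SVM and KNN. For *fused* vectors, the pipeline
additionally scales each descriptor block by `1/sqrt(block length)` after
z-scoring, so every descriptor contributes equally to squared Euclidean
distance. Without this, a 1296-dimension descriptor arithmetically drowns a
40-dimension one regardless of quality: on the synthetic benchmark, fused
HOG+CNN under plain z-scoring scored *between* its two constituents
(five-class accuracy ~0.82 vs ~1.00 for CNN alone), while balanced fusion
restores ~0.99. The forest, invariant to monotone per-feature transforms,
sees raw features.

## Evaluation

`collapse_binary()` maps five-class predictions to diseased (Grades I–IV)
vs healthy. `metrics_paper()` computes, in percent,

* accuracy = (TP + TN) / (TP + TN + FP + FN),
* "precision" = TP / (TP + FN),
* "recall" = TP / (TP + FP),

exactly as the evaluation protocol it reproduces defines them — note the
precision/recall formulas are *swapped* relative to the conventional
definitions, so the standard values are reported alongside as
`precision_std`/`recall_std`. Displayed percentages are **truncated** (not
rounded) to two decimals: that is the convention under which the computed
values match the published report figures digit for digit; full-precision
values are kept in the `*_exact` fields.

The five-way validation scheme splits each class independently into
(train%, test%) = (50,50), (25,75), (30,70), (40,60), (20,80). These cannot
be disjoint folds of one partition, so they are treated as five independent
percentage-split experiments whose test predictions are pooled; classical
stratified k-fold is available via `classical_kfold()`. Train counts are
floored; train and test partition each class in every fold. Within
`evaluate_pipeline()` the CNN is retrained on each fold's training images
only, so no test information leaks into the features, and HOG/LBP (which
are training-free) are computed once per image.

The published report's "Average" and "Standard Deviation" columns have no
stated definition and are not reproduced; the same applies to
execution-time tables and to per-grade accuracies on the external clinical
dataset.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise the pipeline at the scale
the generator's defaults define: 100 images per grade (500 total) for the
end-to-end benchmark, 8 CNN epochs per fold, 100 images for each ROI
property, and 50 random instances per brute-force oracle comparison (at
1e-9 tolerance). Unit tests use smaller datasets (3–20 per grade) chosen
for speed; none of these sizes is a claim about clinical sample sizes.

Other numerical conventions, fixed once and used by both implementations
and test oracles: bilinear resampling maps output pixel `i` to input
coordinate `(i + 0.5) * in/out - 0.5` (half-pixel centres, so exact 2×
decimation equals 2×2 block averaging and outputs are convex combinations
of inputs); HOG orientation is computed as `atan(gy/gx)` folded to
[0°, 180°), identical to `atan2` modulo 180°; box coordinates are 0-based,
row-major, half-open everywhere.

## Limitations

* The phantom's grade signal is deliberately clean; clinical accuracy
  claims cannot be transferred from it.
* The active-contour stage is a standard region-based two-phase scheme, not
  a reimplementation of any specific published contour algorithm.
* The CNN is small and trained per fold from scratch; no pretraining,
  augmentation, or GPU path is provided.
* Multi-scale or rotated template search is out of scope; the matcher
  assumes the joint appears at roughly template scale and orientation.
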