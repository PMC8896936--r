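---
title: "Two-stage rib-fracture recognition on synthetic CT phantoms"
author: "fracturekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage rib-fracture recognition on synthetic CT phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Rib fractures in thoracic CT are small, numerous, and easy to miss on
hundreds of slices.  A practical recognition system has two jobs: find every
suspicious region (high sensitivity), then throw away the inevitable false
alarms (high precision).  `fracturekit` implements this as the classic
two-stage design:

1. **Stage 1 — candidate segmentation.**  A 2D/3D encoder–decoder segmenter
   (U-Net family: skip connections, leaky-ReLU activations with slope 0.01,
   instance normalisation instead of batch normalisation, optional
   coarse-to-fine cascade) is trained on patches under the composite loss

   $$L = L_{\mathrm{dice}} + L_{\mathrm{ce}} + w \cdot L_{\mathrm{contour}},$$

   where $L_{\mathrm{dice}} = 1 - (2\sum pt + s)/(\sum p + \sum t + s)$ is
   the smoothed soft Dice loss, $L_{\mathrm{ce}}$ the mean binary
   cross-entropy, and $L_{\mathrm{contour}} = \frac{1}{|\Omega|}\int_\Omega
   |\nabla H_\varepsilon(\phi)|$ a level-set contour-length penalty in which
   the network's probability field plays the role of the smoothed Heaviside
   indicator $H_\varepsilon(\phi)$.  Whole volumes are predicted by sliding
   windows; overlapping window predictions are fused **per voxel by the
   maximum**, $P_s(v) = \max_i P_{s_i}(v)$.  Thresholding and
   connected-component labelling turn the fused probability into candidate
   regions.

2. **Stage 2 — false-positive exclusion.**  Around each candidate centroid,
   cubic crops of three sizes (default 48/64/80 voxels; any configured
   triplet) are classified by three dense-connectivity 3D networks
   (DenseNet-style blocks with pre-activation units, compressing/pooling
   transitions, global average pooling, single-logit sigmoid head).  Their
   probabilities are fused with weights equal to each classifier's held-out
   validation accuracy,
   $P_c = (\lambda_1 P_1 + \lambda_2 P_2 + \lambda_3 P_3) / (\lambda_1 +
   \lambda_2 + \lambda_3)$, and thresholded.  Stage 2 can only *remove*
   candidates, trading a little sensitivity for a large precision gain.

Instance labels follow the five-value convention of public rib-fracture
annotations: 0 background, 1–4 typed fracture classes, −1 a fracture whose
type could not be assigned.  All non-zero labels are merged into one binary
foreground before segmentation: the task is fracture-vs-background.

## Preprocessing

Preprocessing is fingerprint-driven, in fixed order **resample → clip →
normalize**:

* **Resampling.** The target spacing is the per-axis arithmetic mean of the
  training spacings (overridable).  The stated size rule is dimensionally
  ambiguous as printed in this literature; the package implements the only
  reading that preserves the patient volume:
  `new_size = round(old_size * old_spacing / target_spacing)`.  Images are
  interpolated trilinearly, labels and masks by nearest neighbour (label
  interpolation must not invent values).
* **Intensity clipping.** The clip window is the 0.5th/99.5th percentile of
  Hounsfield values pooled over all *foreground* voxels of the training set,
  with linear interpolation between order statistics.
* **Z-scoring.** Per-sample mean/SD after clipping (the normalisation is
  defined per 3D sample).  Near-constant volumes (SD < 1e-8) are rejected
  rather than silently amplified.

Whether clipping precedes or follows resampling is not prescribed by the
source material; resample-first is chosen and fixed, because the fingerprint
statistics then refer to the same grid the network sees.

## The phantom world

Real rib-fracture CT cannot ship with a desk-scale package, so every stage is
exercised on seeded synthetic phantoms.  The generator's defaults are a
stated world, fixed once:

| parameter | default | rationale |
|---|---|---|
| grid | 64³ voxels | desk-scale excerpt of a chest volume |
| spacing | 1.25 × 0.74 × 0.74 mm | typical reconstructed CT anisotropy |
| background | −50 HU | soft tissue |
| ribs | +700 HU, 3 curved tubes | cortical bone density; arcs in the axial plane with sagittal drift |
| lesions | +200 HU, radius 2–4 mm, attached to a rib | callus-like density between soft tissue and bone |
| noise | 20 HU Gaussian | realistic reconstruction noise |
| uncertain labels | 20% get −1 | mirrors doubtful annotations |
| decoys | 2 blobs at lesion HU, placed off-rib | confusers only context can reject |

Lesions are placed by rejection sampling on rib voxels (guaranteeing bone
attachment) with at least one maximum lesion diameter between centroids, so
the connected components of the label volume correspond one-to-one to the
catalogue; placement failure after 100 retries raises an explicit error.
Decoys share the lesion intensity and appear **only in the image** — they are
exactly the kind of false positive stage 1 is expected to propose and stage 2
to reject.

What the phantoms do *not* emulate: anatomy (rib counts, cortical/trabecular
structure), CT acquisition physics (beam hardening, streaks), partial-volume
blur at interfaces, or the morphological variety of real fracture types
(labels 1–4 are interchangeable tags here).  A green end-to-end test
establishes that the pipeline's machinery — preprocessing, losses,
optimisation, fusion, candidate logic, metrics — works and that context-based
false-positive exclusion functions on bone-attachment cues; it says nothing
about clinical performance.

## Numerical choices

* **Contour loss discretisation**: central differences in the interior,
  one-sided at patch borders, voxel units; the exact adjoint stencil is used
  for the analytic gradient, with subgradient 0 where the gradient magnitude
  vanishes.  Probabilities are clamped to `[1e-7, 1 - 1e-7]` inside the
  cross-entropy.
* **Dice smoothing** defaults to 1 (per patch, averaged over the batch).
* **Optimizer**: RMSprop (momentum-free adaptive, decay 0.9, eps 1e-8) with
  per-element gradient clipping at ±5; the source material does not state an
  optimizer, so the simplest reproducible adaptive baseline is used and
  every training knob is config-exposed.
* **Weight initialisation**: He-scaled Gaussians, fully seeded; every RNG
  stream is derived from one global seed by stage-name hashing, so adding a
  stage never perturbs earlier stages' draws.
* **Sliding windows**: stride `round(patch·(1−overlap))`, last origin clamped
  to the volume edge; default overlap 0.5 and threshold 0.5; 26-connectivity;
  no size filter by default (none is stated in the source), though profiles
  may set one.
* **Surface metrics**: a surface voxel is a foreground voxel with a
  background 6-neighbour, the volume border counting as background;
  distances are Euclidean in mm.  `hd95` is reported in *both* conventions:
  the literal `0.95 × HD` and the common 95th percentile of pooled directed
  distances.  Two empty masks define Dice = IoU = 1 and distances 0, with a
  warning.
* **Fusion weights**: the printed stage-2 combination is an unnormalized
  weighted sum that can exceed 1; since it is used as a probability, the
  package normalizes by the weight total by default and keeps the literal
  form behind `normalize = FALSE`.

## Open design points, decided

* The level-set field φ is never bound to the network output in the source;
  the predicted probability is identified with $H_\varepsilon(\phi)$
  directly (standard for active-contour losses), so ε has no separate knob.
* Stage-2 training candidates: mined from the segmenter's own proposals on
  the training volumes (default), topped up with ground-truth positives or
  random negative crops only if a class is entirely missing; a
  `gt_plus_random` mode exists for comparison.
* Validation split for the fusion weights: 25% of labelled candidates,
  stratified by label, seeded.
* 2D networks are implemented as 3D networks with a singleton slice axis and
  in-plane kernels — one code path, identical semantics.

## Desk-scale profile and budgets

`tinyPipelineConfig()` runs the whole system in minutes on one CPU: 20
phantoms (14 train / 6 held out), a 16³-patch segmenter (2 pooling levels, 4
base channels, 120 epochs × 10 steps × batch 2, lr 1e-3 — stage-2 quality
depends directly on stage-1 components being lesion-sized, so the segmenter
gets the larger share of the budget), candidate filtering at 10 voxels
(≈ one fifth of the smallest lesion's volume), and growth-8 dense
classifiers on 12/16/20-voxel crops (15 epochs, lr 5e-3, class-balanced
cross-entropy since mined candidates run ~2:1 negative).  The
full-scale configurations (96×160×160 patches with [4,5,5] poolings, 512²
2D with [7,7]) ship as constructible presets but are not trainable at desk
scale — that is a deliberate non-goal, as is reproducing published
full-dataset accuracy figures, which require the external data and GPU
training.

## Known limitations

* The conv-net engine is deliberately minimal (no augmentation by default,
  no ensembling, no test-time augmentation, no automatic architecture
  planning); it exists so the pipeline is testable end to end, not to be a
  training framework.
* NIfTI support covers axis-aligned geometries only; oblique affines are
  rejected loudly rather than resampled.
* Images are stored as float32 on disk: voxel round-trips are exact to
  storage precision; labels (int8) and geometry round-trip bit-exactly.
* Surface-distance kernels are exact all-pairs computations — fine for
  lesion-scale masks, quadratic for organ-scale ones.
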