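---
title: "Segmenting and diagnosing lung nodules on 3D CT with residual networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and diagnosing lung nodules on 3D CT with residual networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

Lung nodules are small rounded lesions whose early detection and
benign/malignant triage drives lung-cancer screening. On CT they live inside
the lung parenchyma — a low-attenuation region (around -850 HU) surrounded
by soft tissue (around +40 HU) — and range from under 5 mm ("micro") to
over 30 mm ("mass"). `lungnodenet` implements a two-stage volumetric CAD
pipeline:

1. **Detection**: morphological extraction of the lung parenchyma, windowing
   and resampling onto a common anisotropic grid, splitting each case into
   two 48 x 192 x 192 subcases, and voxelwise segmentation of nodules by a
   **3D residual U-Net**.
2. **Diagnosis**: cropping a 16 x 48 x 48 region of interest around each
   detected nodule and classifying it as benign or malignant with a
   **modified 3D ResNet50**.

Because clinical CT archives cannot ship with a package, every stage is
exercised on synthetic CT phantoms with exactly known lung masks, nodule
masks, diameters and benign/malignant trait labels.

## Preprocessing

CT volumes are normalized with the lung window (-1000..400 HU mapped
affinely onto [0, 1]). The parenchyma mask is computed by a fixed-threshold
binarization at **-320 HU** (the threshold separates aerated lung from soft
tissue and is a standard lung-CT choice; the workflow itself does not
prescribe a value), followed by removal of components touching the volume
faces (ambient air and the air around the bed), retention of the largest
one or two interior components (a second component is kept when it reaches
20% of the first, covering both separate and touching lungs), per-axial-slice
hole filling (vessels and nodules appear as high-density holes), and a
morphological closing with an ellipsoidal element of **4.5 mm physical
radius** scaled by the voxel spacing.

Volumes are resampled to **3 x 1.5 x 1.5 mm** (axial, coronal, sagittal) by
trilinear interpolation — masks by nearest neighbour — with output shape
`round(shape * spacing / target)`. Each case is split along the axial axis
into two halves, padded with -1000 HU (air, neutral under the lung window)
to 48 x 192 x 192; the transform record maps voxel coordinates both ways.
All coordinates in the package are 0-based (axial, coronal, sagittal)
triples with half-open crop windows.

Multi-rater annotations reduce to a ground-truth mask by **>= 3-rater
consensus** per voxel. Per-nodule malignancy levels (1-5) reduce by the
**median (ties rounded down)**: a median of 1-2 is benign, 4-5 malignant,
and 3 — "uncertain" — is excluded. The median is this package's choice of
rater-aggregation rule; the 1-2/4-5/3 mapping itself is fixed. Nodule sizes
bin at 5, 10 and 30 mm (left-open, right-closed).

## The segmentation network

The 3D Res U-Net is an encoder-decoder with skip concatenation. Each of the
four down-sampling modules is a residual unit followed by 2x2x2 max
pooling; the channel ladder is 8, 16, 32, 64 with a 128-channel bottleneck
unit. Each up-sampling module is a 2x2x2 transposed convolution (+IN+ReLU)
that halves the channels, a concatenation with the same-size encoder map,
and a residual unit that reduces the doubled channels back. The head is a
1x1x1 convolution with a sigmoid.

A residual unit runs `Conv3x3x3 -> IN -> ReLU -> Conv3x3x3 -> IN` on its
mapping path and `Conv1x1x1 -> IN -> ReLU` on its identity path (the 1x1x1
projection is present in **every** unit, matching the per-block listing of
the reference architecture), sums the two and applies a final ReLU.
Instance normalization uses epsilon 1e-5 with per-sample statistics and no
cross-instance sharing. Weights are Xavier-uniform; `shape_table()`
reproduces the reference stage table exactly for a 1 x 48 x 192 x 192
input, and pooling is placed after each unit (unit-then-pool), reading the
printed per-stage sizes as post-pool.

### The switched loss

Soft Dice loss `1 - (2|TP| + s) / (|T| + |P| + s)` is the natural
segmentation objective but is unstable early in training when the
prediction is nearly empty, so the first **3 epochs** optimize summed
binary cross-entropy instead — a warm start whose logit-space gradient is
simply `P - T` — and Dice takes over afterwards. The smoothing constant
`s = 1e-5` guards the empty-mask corner. Two Dice variants are
implemented: the sum-denominator form (the training default) and the
squared-denominator form, whose voxelwise derivative underlies the
documented gradient expression `2T(T^2 - P^2) / (T^2 + P^2)`; that printed
expression equals the squared-denominator derivative rescaled by the
positive factor `(T^2 + P^2)`, and the package validates both against
numerical differentiation. The BCE *value* is the stated sum over voxels;
for optimization its gradient is scaled by 1/N (mean reduction), which is
invariant under Adam's per-parameter normalization but keeps intermediate
quantities well-scaled.

## The classification network

The classifier is a ResNet50 rebuilt for small 3D inputs: bottleneck stages
with block counts (3, 4, 6, 3); **no max-pooling anywhere** (downsampling
only by strided convolutions — the stem max pool would discard detail at
exactly the scale of a nodule); a stem kernel reduced from 7x7x7 to 3x3x3;
and, in the last two stages, depth-sparing **1x3x3** middle kernels that
respect the 16-slice ROI. Stage strides (1,1,1), (1,2,2), (2,2,2), (2,2,2)
leave a 4 x 6 x 6 final grid for the standard ROI, which global average
pooling (retained — it is the head's aggregation, not a pooling *layer* in
the stem sense) reduces for a 2-way log-probability head trained with mean
negative log-likelihood. Exact reduced kernel sizes and the stride pattern
are this package's concretization; the reference only states that kernels
shrink and pooling goes. Normalization is instance normalization throughout
for batch-size robustness. Ties at the decision threshold resolve to
*malignant*, the conservative call.

## Training and evaluation

Reference-scale defaults: segmentation 64 epochs, batch 6, Adam at 1e-2
dropped to 1e-3 and 1e-4 by thirds of the epoch budget; classification 52
epochs, batch 16, Adam at 1e-4. Batches are
accumulated sample-by-sample (exact for instance normalization up to
gradient averaging). Every loop is a pure function of (data, config, seed).

Evaluation reports Dice, precision and recall per connected nodule
(scored inside the component's bounding box with an 8-voxel margin, so one
nodule's error cannot drown another's score), averaged within size
categories; classification reports the confusion matrix at argmax,
accuracy/recall/specificity, and the ROC/AUC over malignant-class
probabilities, where the AUC is the standard rank statistic (threshold
sweep + trapezoid, ties at half credit).

## The phantom generator

Phantoms emulate exactly the features the pipeline depends on: an elliptic
body cylinder (+40 HU) containing two lung ellipsoids (-850 HU) in ambient
air (-1000 HU), an optional bed slab (+200 HU) below the body, optional
tubular vessels (+50 HU), and nodules at -50..+80 HU placed entirely inside
a lung — spheres for the benign trait, spiculated blobs (a 0.9 R core plus
4-10 narrow radial cones reaching 1.2 R) for the malignant trait, keeping
the equivalent-sphere diameter recoverable from voxel counts. Additive
Gaussian noise (default sd 20 HU) is drawn before any flag-dependent
painting, so toggling the bed or vessels changes only the painted voxels —
which is what makes the bed-invariance property exactly testable. Phantoms
do **not** emulate scanner texture, beam hardening, ground-glass opacity or
annotation ambiguity, so passing tests demonstrate algorithmic correctness
and desk-scale learnability, not clinical performance.

Default study conditions: 64 x 128 x 128 voxels at 3 x 1.5 x 1.5 mm, two
nodules of 5-25 mm, malignant fraction 0.5, noise sd 20 HU, bed and vessels
on. The scaled-down segmentation study uses 20 single-nodule 32 x 64 x 64
subvolumes (phantom seeds 1-20, diameters 12-25 mm — all in the "nodule"
size class and above), 15 for training and 5 held out.

## Numerical and desk-scale choices

* The conv engine (im2col + GEMM with a direct stride-1 path, explicit
  backward passes, Adam) is validated against central finite differences to
  1e-6 or better at every layer and end-to-end.
* The segmentation head's bias starts at -4 (sigmoid about 0.018). Nodules
  occupy a fraction of a percent of the voxels, and a symmetric start
  leaves soft Dice on a plateau where the whole background must first be
  pushed down; starting from an almost-empty prediction is the standard
  prior-probability initialization for extreme class imbalance and makes
  convergence seed-robust. Convolution weights remain Xavier-uniform.
* Desk-scale training uses the quarter-width ladder (2, 4, 8, 16;
  bottleneck 32), batch 1, 30 epochs, and the staged schedule mapped onto
  that budget as 1e-2 for the first two thirds and 1e-3 for the rest: on
  CPU-sized cohorts the Dice phase needs the larger step count at 1e-2 to
  clear the background-suppression plateau before any drop. This mapping
  was fixed from the loss-curve shape of the small-batch setting; the
  reference-scale default keeps the three-stage schedule.
* Problem sizes in the test suite: 16^3 volumes for gradient checks,
  32 x 64 x 64 subvolumes and a quarter-width network for the segmentation
  studies, and for the classifier a 30-ROI balanced cohort at 1/16 width
  (nodules of 16-25 mm, so the spiculation trait spans several voxels on
  the common grid) plus an 8-ROI memorization run at 1/8 width. The
  memorization and separability properties stop early once reached
  ("within N epochs" bounds remain honest).
* Degenerate inputs are rejected with diagnostics: all-air volumes (empty
  parenchyma), empty ROI components, single-class ROC, both-empty Dice with
  smoothing disabled, non-finite voxels with their location.

## Known limitations

* Training at full scale (full-width networks, 48 x 192 x 192 subcases,
  clinical-archive-sized cohorts such as LIDC-IDRI) is far outside a CPU budget; the
  package's full-width networks are exercised for architecture exactness
  and inference contracts, while learning properties run at reduced width.
* The DICOM reader covers uncompressed little-endian single-frame CT
  series only; NIfTI is the canonical format.
* Phantom realism is deliberately minimal (see above); in particular the
  malignant trait is purely geometric (spiculation), so classifier results
  on phantoms say nothing about radiomic texture cues.
* Inference on full-width networks allocates the whole feature pyramid in
  memory; slab-wise inference is not implemented.
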