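---
title: "Hemisphere-symmetry-aware 3D CNN segmentation of ischemic stroke lesions from CTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemisphere-symmetry-aware 3D CNN segmentation of ischemic stroke lesions from CTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctaseg)
```

## The problem

Acute ischemic stroke produces a subtle decrease in x-ray attenuation of the
affected brain parenchyma. On a contrast-enhanced CT angiography (CTA) head
volume this hypoattenuation is close to the noise floor — a few Hounsfield
units (HU) against a noise standard deviation of similar magnitude — so a
voxel's raw intensity alone carries little signal. What does carry signal is
*hemispheric asymmetry*: the healthy brain is approximately mirror-symmetric
about the midsagittal plane, so comparing each voxel with its contralateral
counterpart turns a barely-visible absolute change into a detectable relative
one.

`ctaseg` implements an automated pipeline built around that idea:

1. **Preprocessing** — head-region extraction, isotropic resampling, HU
   normalization, and construction of a two-channel representation: the
   volume itself plus a left–right flipped copy co-registered back onto it.
2. **Segmentation** — a deep, valid-padded 3D convolutional network that maps
   two-channel patches to per-voxel lesion probabilities, applied to whole
   volumes by exact tile-and-stitch inference.
3. **Post-processing** — probability thresholding, small-cluster removal, and
   a case-level stroke call from the largest connected lesion volume.
4. **Evaluation** — voxel-wise precision/sensitivity/Dice, volume-threshold
   ROC analysis, stratified bootstrap confidence intervals, and
   volume-agreement regression against reference volumes.
5. **Synthetic phantoms** — a generator of CT-like head phantoms with known
   lesion masks, so the full pipeline is trainable and testable at desk scale
   without clinical data.

## Preprocessing

`extract_head_region()` locates the skull apex (topmost axial slice with at
least 10 voxels above 700 HU — the bone count guards against noise specks)
and keeps the 175 mm below it, inclusive at both ends (351 slices at 0.5 mm).
The inclusive-endpoint convention is a package choice; the extent itself is a
tunable of `run_config()`.

`resample_isotropic()` brings the volume to an isotropic working grid
(default 0.5 mm) by trilinear interpolation, with nearest-neighbour used for
label masks so mask labels are preserved. The output shape per axis is
`round(extent / target)`, preserving physical extent to within one voxel.

`normalize_hu()` maps the 30–60 HU soft-tissue window affinely to [-1, 1]
**without clipping**: values outside the window continue linearly, so bone
and contrast-filled vessels remain informative to the network. The map is
exactly invertible (`denormalize_hu()`), which the tests exploit.

`mirror_register()` builds the second channel. The volume is flipped along
its left–right axis and registered back onto the original in two stages:

* a **rigid stage** maximizing mutual information (32 histogram bins, 2048
  spatial samples, four resolution levels, a 500-iteration budget). The
  joint-histogram metric is locally bumpy, so each level first evaluates a
  coarse grid of candidate rotations around the current estimate and then
  refines with a Nelder–Mead simplex. All metric samples are drawn once from
  a seeded stream, making the whole registration deterministic.
* a **deformable stage**: a free-form cubic B-spline displacement field with
  16 mm control-point spacing, optimized by stochastic gradient descent on
  the squared intensity difference. Both channels come from the same
  acquisition, so a least-squares metric is appropriate for this stage. The
  control grid has more degrees of freedom than one sample set, so the 2048
  metric samples are renewed every iteration (a fixed set would overfit) and
  progress is monitored on a fixed held-out sample set.

If the deformable stage fails to reduce the mean absolute intensity residual
over tissue voxels, it is discarded and the rigid result is kept; a warning
is recorded in the returned provenance. By construction the delivered
mirrored channel is never worse than the rigid-only result. No head mask
restricts the metric; sampling is uniform over the volume.

Whether normalization precedes registration is immaterial for the affine
intensity map itself; the package registers normalized volumes so that one
representation flows through the whole pipeline.

## The network family

The segmentation model is a family of fully-convolutional 3D networks
parameterized by `network_config()`:

* `depth_C` 3×3×3 convolutional layers of `width_F` filters each, **valid
  padding**, exponential-linear activations;
* two-layer skip concatenations: layer `j >= skip_start` receives the output
  of layer `j - 1` concatenated with the output of layer `j - 2` cropped by
  one voxel per side (to align the valid-padded shapes);
* a 1×1×1 layer of 50 filters (ReLU), then a 1×1×1 two-class softmax output;
* no pooling, dropout, or normalization layers anywhere.

Valid padding is the load-bearing choice: every 3×3×3 layer shrinks each
spatial edge by exactly 2, so a network evaluated on overlapping tiles
produces *bit-identical* values to a single whole-volume pass. Tiled
inference (`stitch_predict()`) is therefore exact, not an approximation, and
the package tests this equivalence directly.

The default configuration (`depth_C = 40`, `width_F = 16`, skips from layer
4, 2 input channels) has 527,768 trainable parameters — 528,000 to the
nearest thousand — a theoretical receptive field of 81 voxels, and maps a
107³ patch to a 26³ output. Forty valid convolutions alone would give
27³; the remaining voxel is removed by `terminal_crop = 1`, an asymmetric
one-voxel crop from the high-index side of each axis after the last
convolution. The crop carries no parameters, sits before the softmax, and is
exposed as configuration rather than hard-coded; it reconciles the
valid-padding arithmetic with the published 26³ output contract. Whether the
first convolutional layer participates in a skip concatenation is another
open choice; here it does not (`skip_start = 4`), the placement whose
parameter count rounds to the published total.

Weights are initialized with variance-scaling (fan-in) Gaussian draws and
zero biases from a caller-supplied seed. The implementation (forward pass
and backpropagation) is written in RcppArmadillo; the 3D convolution is
phrased as 27 accumulating matrix products on shifted channel-major views,
which runs at near-DGEMM speed on one CPU core without materializing an
im2col matrix.

## Training

Patches are enumerated by tiling each volume with output-aligned blocks
(stride = output edge by default, i.e. non-overlapping output blocks). A
tile is *positive* when its output block contains at least one lesion voxel
— the threshold is exposed (`min_pos_voxels`) since "contains lesion" is
otherwise ambiguous — and tiles entirely outside the tissue mask are
discarded. At clinical scale this yields counts of the order of thousands of
positives and tens of thousands of negatives per training set.

Class imbalance is handled by construction of the minibatch stream
(`balanced_batch_stream()`): every minibatch holds exactly 4 positive and 4
negative patches. An epoch visits every positive exactly once (seeded
shuffle), hence `ceiling(n_pos / 4)` iterations per epoch — 750 iterations
for 3,000 positives. Negatives are sampled without replacement until the
pool is exhausted, then reshuffled. When the positive count is not a
multiple of the batch size the final batch is topped up with already-seen
positives: the 50/50 balance contract is kept exact in preference to the
exactly-once property, which can only hold simultaneously for divisible
counts.

Optimization is Adam (conventional moment-decay defaults) at learning rate
10⁻⁴ on mean per-voxel cross-entropy over the output block; the loss
supervises every output voxel, patch labels steer only the sampling.
Training halts when the validation loss fails to improve by more than 10⁻⁴
for 3 consecutive epochs (both tunables of `train_plan()`), and the weights
from the best validation epoch are returned. `grid_search()` trains one
network per (depth, width) combination — the published search used
{10, 20, 30, 40} × {8, 16}, eight networks — and ranks them by best
validation loss.

All randomness (initialization, shuffles, negative sampling, registration
samples) flows from caller-supplied seeds; two runs with the same data and
seeds produce identical loss histories and identical probability maps.

## Inference, post-processing, display

`plan_tiles()` covers the volume with output blocks at stride equal to the
output edge; when an axis is not a multiple of the edge, a final shifted
tile covers the remainder. Each tile carries the write region it is
responsible for, and these regions partition the volume — every voxel is
written exactly once, and any overlap between a shifted tile's block and its
predecessor would contain identical values anyway by the valid-padding
equivalence. Input blocks extend `depth_C` voxels beyond each output corner
and are satisfied by padding with the normalized value of −1000 HU (the
border policy is a package choice; the equivalence property makes it
observationally irrelevant away from the physical border).

`binarize()` thresholds at probability ≥ 0.5 (inclusive).
`filter_components()` labels connected clusters — 26-connectivity by
default, 6/18/26 exposed since "continuous cluster" admits several readings
— and removes clusters strictly smaller than 3 mL; a cluster of exactly
3 mL (24,000 voxels at 0.5 mm) is retained. `classify_stroke()` calls a case
a stroke when its largest retained cluster is strictly larger than 25 mL,
the ROC operating point; the threshold is a tunable, not a constant.

For display, `calibrate_colormap()` sets the color range to the 0.05/0.95
quantiles of predicted probabilities inside validation lesion regions, with
the lower bound cut off at 0.5 and a (0.5, 1) fallback for degenerate
samples. `render_overlay()` draws probabilities ≥ 0.5 in a perceptually
uniform plasma palette over the grayscale base; probabilities below 0.5 are
fully transparent. Bit-exactness is required of the probability maps, not of
the rendered images.

## Evaluation stack

Voxel metrics are counted inside the tissue (non-air) mask and pooled across
cases — counts summed first, ratios formed once. Pooling (rather than
averaging per-case ratios) is the convention that pairs naturally with
case-level bootstrap resampling; undefined ratios are reported as missing,
never coerced to zero. Dice equals the harmonic mean of precision and
sensitivity on shared counts, and the tests assert that identity on random
masks.

`roc_volume_threshold()` varies a volume cut-off over the observed values
(rule: stroke when volume > threshold), computes the trapezoidal AUC —
verified against a brute-force pairwise-concordance oracle, ties counting
one half — and picks the operating point closest to the top-left corner,
breaking ties toward the higher threshold (fewer false positives).

`bootstrap_ci()` implements the stratified percentile bootstrap: strokes and
nonstrokes are resampled separately at their original sizes (10⁵ replicates
by default), and the 2.5th/97.5th percentiles of the statistic's bootstrap
distribution form the interval. Cases, not voxels, are resampled — voxel
resampling would ignore within-case correlation. Resamples on which the
statistic is undefined are skipped and counted; more than 1% skips is an
error rather than a silent bias.

`volume_agreement()` reports Pearson's r and a linear regression of
reference volumes on predicted volumes with forced intersection at the
origin: slope = Σ(ref·pred)/Σ(pred²), with the average relative volume
difference (slope − 1)·100% (positive meaning the reference source produced
larger volumes) and paired-bootstrap CIs.

## The synthetic phantom generator

`phantom_spec()` / `generate_phantom()` build a digital head in physical
units: air background at −1000 HU, an ellipsoidal ~1000 HU skull shell
leaving a 2-voxel air margin, noisy parenchyma (42 ± 4 HU, kept inside a
10–80 HU plausibility band so the normalization window stays meaningful),
a symmetric pair of ~8 HU CSF ventricles, and an optional unilateral
ellipsoidal lesion whose mean attenuation is reduced by `lesion_delta_hu`
(default 6 HU — subtle, so that the contralateral channel is genuinely
needed) with its exact binary mask returned. Optional extras emulate the
dominant clinical confounders: paired low-HU bands adjacent to the skull in
the temporal/posterior regions (beam-hardening-like, a known false-positive
source) and a rigid pose perturbation. The noiseless anatomy is
mirror-symmetric by construction, which the symmetry tests rely on.

`generate_cohort()` derives per-case sub-seeds, sides, lesion shapes and
positions deterministically from one master seed; stroke cases draw target
volumes uniformly from a requested range and controls have empty masks. The
desk-scale study conditions are fixed once: 54³ voxels at 2 mm isotropic
(108 mm field), which keeps a 20–40 mL lesion comfortably inside the brain
compartment and a full train/validate/test experiment within minutes on one
CPU core.

What the phantoms deliberately do **not** model: photon transport or
sinogram-level physics, vascular trees and contrast dynamics, perfusion,
gyral/sulcal texture, or pathology other than a smooth hypoattenuating
ellipsoid. Tests passing on phantoms therefore demonstrate that the
*machinery* is correct — geometry, registration behavior, learning dynamics,
metric identities, determinism — not that the trained weights transfer to
clinical CTA. Clinical-scale performance figures for this method were
measured on data that is not available; the package reproduces such figures
only where they reduce to computations on printed inputs (the tests verify,
for example, that a 43/5/45/7 case confusion gives accuracy 0.88 and that
precision 0.69 with sensitivity 0.54 implies Dice 0.61), and otherwise
replaces them with property-based checks and a scaled-down
parameter-recovery experiment (a small network trained on 20
phantoms with pronounced 30 HU lesions, expected to reach held-out voxel
Dice ≥ 0.5 and cohort ROC AUC ≥ 0.9).

For that scaled-down run the training hyper-parameters are chosen for the
desk scale: learning rate 10⁻³ (the clinical run's 10⁻⁴ is matched to its
~22,500-iteration budget; the desk run has two orders of magnitude fewer
iterations), at most 8 epochs with patience 2, batches 4+4 as always.

## Numerical choices and degenerate inputs

* Normalization round-trips to 10⁻⁶; stitching equivalence is asserted to
  10⁻⁵ (double precision end to end).
* Softmax is computed with max-subtraction; cross-entropy floors
  probabilities at 10⁻¹² before the log.
* Interpolation clamps to the grid for resampling (constant volumes stay
  constant) and fills with air for registration and padding.
* Degenerate inputs fail loudly with named errors: no skull, all-air
  volumes, empty probability samples, single-class ROC input, degenerate
  agreement variance, zero positives in a training set.
* `run_config()` defaults reproduce every published constant; the
  configuration hash (MD5 of the canonical JSON) is carried in every written
  artifact, so re-running with any altered constant is detectable.

## Known limitations

* Input is NIfTI only; DICOM series conversion is not implemented in this R
  stack.
* The registration optimizer is a deterministic grid-seeded simplex plus
  stochastic descent, tuned for the mirror-registration problem (moderate
  misalignments); it is not a general-purpose registration tool.
* Training is single-threaded double-precision CPU code: appropriate for the
  desk-scale experiments the package targets, far from what the clinical
  configuration (40 layers, 107³ patches, 30 epochs) would need.
* Reference volumes are treated as opaque numbers; nothing perfusion-related
  is computed.
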