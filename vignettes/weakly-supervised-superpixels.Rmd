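---
title: "Weakly supervised tumor segmentation with deep superpixel generation and clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised tumor segmentation with deep superpixel generation and clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pixel-level tumor annotations are expensive; image-level labels ("this slice
contains tumor: yes/no") are cheap. `spixelseg` trains a segmentation model
for focal brain lesions in multimodal MR slices using only those binary
labels. The method rests on three ideas:

1. **A classifier knows where it looks.** A convolutional tumor-presence
   classifier trained on the binary labels is probed with randomized input
   sampling (RISE): many random soft masks occlude the image, the
   classifier's probability on each masked copy weights that mask
   (the canonical weighted-average accumulation, normalized by
   `K * keep_prob`; no subtraction of the unmasked score), and the
   accumulated map scores every pixel's importance. Per image, the top 20%
   of pixels become *positive seeds*, the bottom 20% *negative seeds*, and
   the middle 60% stays unseeded. Seeds deliberately **undersegment**: positive
   seeds sit inside tumors, negative seeds inside healthy tissue, and the
   uncertain band between them absorbs classifier error instead of
   propagating it.
2. **Superpixels carry boundary information.** A fully convolutional
   *generator* assigns every pixel a probability simplex over `N_S` global
   superpixel candidates (association map `Q`). A *clusterer* consumes the
   image concatenated with `Q` and emits a simplex of per-superpixel tumor
   scores `R`. The soft-clustered tumor heatmap is
   `H+(p) = sum_s Q[s, p] * R[s]`, a convex combination, so `H+` is a valid
   per-pixel probability by construction.
3. **Train both nets jointly against the seeds and the image.** The
   objective is `L = L_spixel + alpha * L_seed`.
   `L_spixel = sum_p ( ||f(p) - sum_s u_s Q[s,p]|| + m ||p - sum_s l_s Q[s,p]|| )`
   (mean over the images of a batch) makes superpixels compact in intensity
   and space, where `u_s`, `l_s` are the soft mean intensity and location of
   superpixel `s`. `L_seed` is the cross-entropy of `H+` against the seeds,
   normalized by the seeded pixel count. Gradients reach the generator both
   directly and through the clusterer's input, so the two models shape each
   other.

At inference, the heatmap is thresholded (threshold chosen on the validation
cohort by a 0.1-step grid search on mean Dice), and slices the classifier
calls healthy receive empty masks.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 50 | weight of the seed loss; larger values trust the classifier's seeds more, at the cost of intensity coherence. The reference protocol pairs `alpha = 50` with a selected threshold near 0.6. |
| `m` | 3/160 | prices the spatial spread of a superpixel (per pixel of distance, in raw pixel units) against intensity spread; calibrated for raw 0-based pixel coordinates at the 128 px scale. |
| `N_S` | 64 | superpixel budget. Training typically leaves most candidates unused (see `count_effective_superpixels()`); the budget matters mainly for multi-lesion images. |
| RISE `K` | 4000 | number of occlusion masks shared by all images; the desk profile uses 500 at 32 px, which keeps the Monte-Carlo error of the 20% quantiles well below the seed-band width. |
| RISE cell grid / keep prob | 8 / 0.5 | the canonical construction: an 8x8 Bernoulli(0.5) grid, bilinearly upsampled with a random sub-cell shift; heatmaps are normalized by `K * keep_prob`. |
| seed quantile | 0.2 | fraction of pixels per seed class. Fixed by the reference protocol; it is intentionally *not* adapted to lesion size, which is what makes seeds undersegment. |
| classifier threshold | 0.5 | gates both the training-time seed override and the inference-time empty-mask override. |
| smoothing | 1 | Dice and U-Dice smoothing; two empty masks score Dice 1. |

Training protocol (both stages): Adam with betas (0.9, 0.999), eps 1e-8,
weight decay 0.1 (L2 added to the gradient), batch 32, 100 epochs, initial
learning rate 5e-4. The classifier decays its rate by 10 when the
validation loss fails to improve by 1e-4 (at most 3 decays); the joint
superpixel stage halves its rate every 25 epochs.

## Study profiles

`run_config(profile = "paper")` carries the reference protocol: 128x128
four-channel slices, a VGG-16-bn classifier (adapted: 4 input channels, a
global-average-pool head instead of the original fully connected stack,
trained from scratch), a ResNet-18 clusterer, `N_S = 64`, `K = 4000`.
Training it is a GPU-scale undertaking.

`run_config(profile = "desk")` is this package's own CPU study design, used
by the test suite and the acceptance script: 32x32 phantoms (256 train / 64
validation / 64 test), `small` three-block backbones (width 8), a width-8
encoder-decoder generator, `N_S = 16`, `K = 500`, 30 classifier epochs
(the plateau schedule settles by epoch 15-20 at this scale; the reference
protocol trains for 100) and 15 joint epochs. The RISE cell grid is 4 at
32 px — scale-consistent with the canonical 8x8 grid on 128-224 px images,
keeping occlusion cells at the lesion-radius scale, which is what makes the
occlusion scores informative. These sizes keep a full run in the
ten-minute range on one core while every stage still has to learn
something nontrivial.

## The phantom generator

`generate_phantom()` emulates the features of preprocessed multimodal MR
slices that the method actually exploits:

* a bright "brain" disk on dark background with smooth, spatially
  correlated texture; the four channels share a low-frequency field
  (70% shared, 30% channel-specific), mimicking multimodal redundancy that
  the intensity term of `L_spixel` relies on;
* focal lesions as unions of 1-3 overlapping ellipses - so superpixel
  boundaries are genuinely curved, not circles - brightened per channel with
  the largest offset on channel 4 (T2-FLAIR-like);
* additive Gaussian noise on a **fixed, clamped \[0, 1\] intensity scale**.
  The scale is deliberately not per-image min-max: normalizing each slice by
  its own extremes would make healthy backgrounds systematically brighter
  than lesion-image backgrounds, letting a classifier read the label off
  global intensity instead of the lesion — a shortcut real volume-level
  normalization does not offer, and one that silently breaks
  occlusion-based saliency;
* an exact lesion-presence fraction (`round(prevalence * n)`), defaulting to
  0.7, near the cancerous fractions of the BraTS-style cohorts.

It does **not** emulate anatomy (no tissue classes, no ventricles), MR
physics (no bias fields, no modality-specific contrast mechanisms), or
non-focal pathology. A pipeline that passes the phantom study therefore
demonstrates that the machinery works end to end - seeds localize bright
focal lesions, superpixels contour them, the threshold transfers from
validation to test - not that it reaches any particular accuracy on real
BraTS volumes.

## Numerical and convention choices

* **Superpixel loss form.** The compactness loss is implemented in its
  reconstruction form (distance of each pixel's intensity/position to its
  association-weighted superpixel moments). A literal transcription without
  the reconstruction target would be minimized by all-zero moments and is
  degenerate.
* **Unsquared norms.** Per-pixel distances are unsquared Euclidean norms,
  following the loss family the coefficient `m = 3/160` was calibrated for;
  the gradient at zero distance is smoothed (`sqrt(x + 1e-12)` in the
  backward pass only), so values are exact and gradients bounded.
* **Seed-loss floor.** Logs are floored at `eps = 1e-7`, below any
  meaningful probability resolution.
* **Seed ties.** Quantile seeds break ties in stable raster (column-major)
  order, making seed maps deterministic for any heatmap, including constant
  ones.
* **Thresholds are `>=`.** Both the classifier gate and the heatmap
  threshold count equality as positive; threshold-grid ties resolve to the
  *larger* threshold (less-segmented, precision-leaning output).
* **Threshold selection uses validation masks**, as the reference protocol
  does. This is a deliberate weak-supervision leak confined to one scalar;
  `select_threshold(..., unsupervised = TRUE)` substitutes a fixed 0.5 for
  fully label-free operation.
* **HD95 is directed** (proposal boundary to reference boundary), per the
  adopted definition, with linear-interpolation percentiles, 4-neighbor
  boundaries, pixel units, and 0 for empty masks; `symmetric = TRUE` gives
  the max of the two directed values as most BraTS tooling reports.
* **Percentile normalization** is per channel per volume over nonzero
  voxels (type-7 linear interpolation); constant channels fall back to
  mapping nonzeros to 1 with a warning.
* **Cohort split** floors the training fraction, rounds the validation
  fraction, and gives the remainder to test (369 patients at 80/10/10 ->
  295/37/37), always at patient level.
* **Patching is per-slice 2D.** Volumes are cropped, normalized, and
  axially sliced first; the random (train) or center (eval) 128 px window
  is then drawn per 2D slice, with one window shared by all four channels
  and the reference mask. Random windows are train-time augmentation only.
* **Argmax ties** in effective-superpixel counting resolve to the lowest
  superpixel index.
* **Batch conventions.** The per-image sums of both loss terms are averaged
  over the images of a batch; pixel coordinates are raw 0-based (row, col)
  indices (the losses are translation-invariant, so the origin convention
  only affects reported moments).
* **Generator architecture.** The generator realizes "global associations"
  as a compact encoder-decoder FCN with skip connections and an
  `N_S`-channel 1x1 head at full resolution, softmaxed per pixel. Inputs
  must be divisible by 4 (two pooling stages). Any FCN meeting this forward
  contract can be substituted; the tests target the contract, not the
  internals.
* **From-scratch training.** No pretrained weights anywhere; first-layer
  channel counts are simply widened to 4 (classifier) or `4 + N_S`
  (clusterer).
* **The NN core.** The package ships a compact tape-based reverse-mode
  autodiff engine over R arrays with C++ kernels (im2col convolution,
  pooling, batch norm). Its gradients are property-tested against central
  finite differences at tolerance 1e-3 on 8x8 toys (observed agreement is
  far tighter).

## Known limitations

* Superpixels are intensity-driven: diffuse or non-focal pathology will not
  be contoured well, and lesions must be distinguishable in at least one
  channel.
* The pipeline is not end-to-end: without a usable classifier the seeds,
  and hence everything downstream, fail. Seed quality is the dominant
  failure mode.
* The desk profile's 32 px resolution limits boundary fidelity; HD95 values
  at that scale are not comparable to 128 px results.
* 2D only: volumes are segmented slice by slice.
* Runtime: the RISE stage scales as `K x` (cohort size) classifier forward
  passes and dominates desk-profile wall time.
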