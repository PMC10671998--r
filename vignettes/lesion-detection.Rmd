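---
title: "Transformer lesion detection in speckled B-scans: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transformer lesion detection in speckled B-scans: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octdetect)
```

## The problem

Optical coherence tomography (OCT) produces cross-sectional B-scans whose
coherent illumination carries multiplicative speckle noise; lesions (for
instance carious regions in dental scans) appear as localized intensity
anomalies inside a layered tissue background. `octdetect` implements a
single-class detector for such scans: every image is mapped to a fixed-size
array of `K` axis-aligned bounding boxes in normalized coordinates
(`x_min, y_min, x_max, y_max`, origin top-left), with all-zero sentinel rows
padding the array where fewer than `K` lesions exist.

Because real annotated speckle-scan datasets are rarely shareable, the
package carries its own synthetic B-scan generator, so the full train /
evaluate / predict loop runs end-to-end with no external data. The network,
its analytic backpropagation and the Adam/AdamW optimizers are written in
base R matrix algebra; there is no deep-learning runtime behind the package.

## Model

The detector is a composition of two stages.

**Attention-gated patch encoder.** The (resized, per-image standardized)
scan is cut into non-overlapping `P x P` patches (`P = 32` by default; the
image is edge-replicated up to the next multiple of `P`), giving `N` patch
tokens in row-major order. A second, "sliding box" stream re-windows the
same padded image with 50% overlap (stride `P/2`) and is resampled by
nearest index to length `N`. Both streams are linearly embedded to the
latent dimension; a gating attention computes row-stochastic weights
`softmax(Q Kᵀ / sqrt(d))` with queries from the sliding-box stream and
keys/values from the input stream, so foreground patches are up-weighted by
content matching. The score-weighted values are reshaped onto the token
grid, passed through two 3x3 convolutions (filters 32 and 64, stride 3,
edge-replicated padding, GELU) whose strided output is upsampled back to the
grid by nearest neighbor so the token count never changes, and finally
through a single-head self-attention layer.

**Transformer trunk and box head.** A learnable summary token is prepended
and learned positional embeddings are added (`(N+1) x D`). Each of the
`n_blocks` pre-norm transformer blocks applies
`z' = z + MSA(LN(z))`, `z = z' + MLP(LN(z'))` with multi-head
self-attention, a GELU MLP and dropout. After a final LayerNorm, an MLP head
reads the summary token and emits `4K` sigmoid outputs; each box's
coordinate pairs are sorted so `x_min <= x_max` and `y_min <= y_max` always
hold. The scaled-dot-product logits carry the `1/sqrt(d)` factor throughout
for numerical stability.

Defaults: 8 blocks (the desk-scale studies below use 2), 4 heads, latent
dimension 64, MLP widths `(128, 64)`, dropout 0.1, `K = 3`, and a working
resolution of 250 x 250 — a config parameter, since acquisition pipelines
deliver anything from ~250 to ~500 px per side. An optional
`denoiser` hook (a function `matrix -> matrix`, identity by default) lets an
external speckle denoiser run before patching.

## The composite loss

Training minimizes, per image, the mean of three `[0,1]`-bounded components
on index-aligned box arrays (ground truth is canonically sorted by
`(y_min, x_min)` with sentinels trailing):

* `L_MSE` — mean squared coordinate difference over all `4K` slots, so
  superfluous predicted boxes are pulled toward the zero box;
* `L_difference` — `1 - SSIM` between soft rasterized box masks: each array
  is drawn as the pixelwise-max union of exact per-pixel coverage profiles
  (piecewise linear in the coordinates) and blurred with a Gaussian
  (`sigma = 2` px), then compared by mean local SSIM (uniform 7x7 window,
  `K1 = 0.01`, `K2 = 0.03`, data range 1, sample covariance, 3-px border
  crop — the standard formulation, cross-checked in the tests against
  scikit-image);
* `L_IOU` — one minus the mean intersection-over-union over index-aligned
  pairs in which at least one side is non-sentinel.

Inside the loss, "sentinel" is a zero-area test with tolerance `1e-4` (the
same cutoff prediction uses): a sigmoid head can shrink a surplus box
arbitrarily but never to exactly zero area, and without the tolerance the
IOU term would have a hard floor on images with fewer lesions than slots.
A structural-similarity difference between "predicted and actual" content
admits more than one reading (image crops could be compared instead of
masks); rendering the box arrays as soft masks was chosen because it is
computable from boxes alone and smooth in the coordinates, and it is
documented here as a design interpretation.

All three gradients are analytic. The IOU surface is flat for disjoint boxes
(the MSE term supplies the travel signal, as intended — no generalized-IOU
substitution is made), and the structural term differentiates through the
SSIM statistics, the blur (a transposed banded-matrix product) and the
coverage profiles. `lloss_grad` is verified against central finite
differences of `lloss` in the test suite, and full-network backpropagation
is verified the same way at a tiny configuration (worst relative error
around `1e-6`).

## Evaluation protocol

Evaluation is single-class: predictions and ground truth are matched
greedily in descending IOU (each prediction used at most once; unmatched
ground-truth boxes score IOU 0), a matched pair with IOU strictly above 0.5
counts as a true positive and anything else as a false positive, and true
negatives and false negatives are fixed at zero. Two identities follow and
are asserted in the tests: accuracy equals precision on every evaluation,
and sensitivity equals 1 whenever at least one pair exists (an IOU of
exactly 0.5 counts as FP — the strict-greater TP rule). Mean IOU
is reported over all matched pairs, with the per-image IOU lists retained in
the report.

## The synthetic generator

`generate_scan` emulates the geometry of layered-tissue B-scans:

* a stack of `n_layers` horizontal intensity bands with smooth, wavy
  (sinusoidally perturbed) boundaries, lightly blurred;
* one or more axis-aligned elliptical lesions with Gaussian-soft edges
  (`sigma = 2` px) and a signed intensity offset, placed fully inside the
  image with mild rejection sampling against heavy overlap; the lesion count
  is uniform on `lesion_count_range` (default 1–3 per image);
* fully developed speckle as multiplicative gamma noise with mean 1 and
  shape `k`, so the speckle contrast is `1/sqrt(k)` (default `k = 4`,
  contrast 0.5 — harsh but realistic for raw B-scans).

Each scan's ground truth is the tight bounding box of its lesion's perturbed
pixels (soft mask above 0.1), so boxes are exact by construction. A
`(seed, index)` pair determines each scan bit-exactly without touching the
caller's RNG stream. Default geometry mirrors the nominal 500 x 412 px
B-scan; the desk-scale studies use 128 x 128.

What the generator does *not* emulate: physically accurate A-scan formation,
depth-dependent attenuation, refraction at tissue interfaces, 3-D volume
context, or the appearance statistics of real carious lesions (clinical
SD-OCT datasets are typically private, and no quantitative model of lesion
appearance is available — generator realism is heuristic by necessity).
Green tests on
synthetic data therefore demonstrate the correctness of the pipeline's
mechanics, not clinical performance.

## Augmentation

`augment` applies an affine map about the image center — optional
left-right flip, rotation uniform in ± (0.02 of a full turn, i.e. ±7.2°, the
conventional semantics of a "rotation factor"), and isotropic zoom uniform
in 1 ± 0.2 — to the image (bilinear resampling through the inverse map,
edge replication) and pushes every box through the same forward map as the
axis-aligned hull of its transformed corners, clipped to the unit square;
boxes that lose more than 90% of their area are replaced by sentinels.
"Flipped about the horizontal axes" is read as a left-right flip and is
toggleable. Draws can be passed explicitly (`draws =`) for reproducibility
and for exercising the involution properties in tests.

## Training

`octdetect()` is the single fitting entry point: Adam (or AdamW) on the mean
composite loss over shuffled batches (defaults: learning rate `5e-4`, batch
size 4, 200 epochs), one integer seed controlling
initialization, shuffling, augmentation draws and dropout, optional
validation-split tracking with best-state retention, and RDS checkpoints
that restore bit-identical inference. Augmentation is opt-in
(`augment = augment_params()`, two draws per record per epoch by default).
The structural loss term is rasterized on a 64 x 64 grid during training — a
resolution/cost compromise; the grid is a `train_control` parameter.

### Numerical and initialization choices

* **Per-image standardization.** Patches of raw `[0,1]` intensities share a
  dominant mean component that makes their embeddings nearly parallel and
  washes out every attention logit; inputs are standardized to zero mean and
  unit variance per image before patching.
* **Low-frequency embedding basis.** Patch embeddings initialize from a 2-D
  cosine basis ordered by total frequency (plus 10% Glorot noise). Speckle
  is high-frequency; lesions and tissue bands are smooth, so the earliest
  training signal flows through speckle-robust coarse modes (the first mode
  is the patch mean).
* **Content-matching attention start.** The gate's two embedding maps, and
  the final encoder attention's query/key maps, share initial weights, so
  initial logits are Gram matrices: diagonal-dominant, hence near an
  identity operator rather than a uniform average that would collapse all
  tokens onto the patch mean. The final attention's value/output maps start
  identity-biased for the same reason.
* **Edge-replicated conv padding** keeps a constant feature map constant
  under the token-grid convolutions (no border artifacts), consistent with
  the padding convention used everywhere else in the package.
* LayerNorm uses `eps = 1e-6`; ties in coordinate sorting and in greedy
  matching resolve to the first index; degenerate (area `< 1e-4`) predicted
  boxes are reported as sentinels.

## Desk-scale studies, and what they show

The test suite and `scripts/acceptance.R` run two studies sized for a single
CPU (the methods are identical at any scale; these sizes keep the full suite
within minutes):

1. **Optimization sanity (overfit one batch).** A 4-image batch, the default
   model with 2 blocks, dropout and augmentation off (the standard practice
   for an overfit check — regularization defeats its purpose), 800 Adam
   steps at the default learning rate. The composite loss falls to ~3–5% of
   its initial value, demonstrating that the loss, its analytic gradients,
   backpropagation and the optimizer work end to end. Note that a budget of
   a few hundred steps is a *displacement* requirement: Adam moves each
   parameter by at most ~`lr` per step, so meaningful output changes need
   `steps x lr` of order 1.

2. **End-to-end recovery.** 500 synthetic 128 x 128 single-lesion scans,
   split 60/10/30, 2-block model, 30 epochs. This study is reported honestly
   as a negative result at this scale: training remains at the unconditional
   optimum (predicting the same, eventually degenerate, boxes for every
   image) and held-out mean IOU does not exceed the untrained baseline. Two
   mechanisms interact: at the unconditional optimum the composite loss
   *prefers* near-empty predictions (an empty mask scores a high SSIM
   against a sparse ground-truth mask, and the IOU term is flat for disjoint
   boxes), and escaping that optimum requires extracting a speckle-buried
   localization signal through a stack of freshly initialized linear stages
   — a plateau that a full-scale training regime (hundreds of epochs over
   thousands of images on accelerator hardware) can cross but a 2 250-step
   desk-scale budget cannot. The overfit study shows the same model and loss do learn
   when the step budget is adequate.

## Limitations

* Detection quality claims require training at full scale; the
  package ships the mechanics (verified by oracles and invariants), not a
  pretrained model.
* The structural loss's mask reading is one of several defensible
  definitions of a structural-similarity difference between detections.
* The evaluation protocol's `TN = FN = 0` accounting makes sensitivity
  uninformative by construction (always 1) and accuracy a synonym of
  precision; both identities are asserted rather than hidden.
* Single-channel 2-D scans only; no DICOM or vendor OCT formats; no
  objectness scores, anchors or non-maximum suppression (the box array is
  fixed-size by design).
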