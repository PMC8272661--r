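---
title: "Deformable U-Net segmentation: model, losses and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable U-Net segmentation: model, losses and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dunet)
```

## The problem

The pancreas is one of the hardest abdominal organs to segment on CT: it
occupies well under 1% of a slice, its soft-tissue intensity barely differs
from its surroundings, and its shape, size and position vary strongly across
patients. This package implements a slice-wise, semiautomated segmentation
pipeline built around a *deformable U-Net* (DUNet): human-annotated
coordinate extremes localize the organ coarsely, and an encoder–decoder
network whose second and third resolution levels use deformable convolution
refines the region into a voxel mask. Everything — the deformable operator,
the network, the class-imbalance-aware loss family, the metrics and the
preprocessing — is implemented from first principles in this package (the
convolution kernels and their hand-derived backward passes in compiled code),
because no deep-learning framework is part of its dependency set.

## Deformable convolution

Standard 2D convolution samples a fixed grid: for a 3×3 kernel with dilation
1 the grid is the nine displacements $\{-1,0,1\}\times\{-1,0,1\}$ around each
output pixel, and

$$Y(p_0)=\sum_{p_n\in\mathcal{G}} W(p_n)\,X(p_0+p_n),$$

with zero padding outside the image (`standard_conv2d()`, pad $k/2$, stride
1, so output and input dimensions agree). Deformable convolution adds a
learned displacement to every sampling position:

$$Y(p_0)=\sum_{p_n\in\mathcal{G}} W(p_n)\,X(p_0+p_n+\Delta p_n(p_0)),$$

where the offsets $\Delta p_n$ — one (vertical, horizontal) pair per kernel
point and output pixel, $2k^2$ channels in total — are produced by an
ordinary convolution over the same input (`conv_offset_layer()`). Offsets
are fractional, so displaced positions are read with bilinear interpolation
(`bilinear_sample()`), which also makes the operator differentiable in the
offsets. Two conventions the literature leaves implicit are fixed here:

* **Additive cross-correlation.** The indexed form of the deformable sum can
  be written with sign-flipped taps (true convolution); we implement the
  additive convention used by the operator's reference implementations and
  by deep-learning practice throughout, so the zero-offset case coincides
  exactly with `standard_conv2d()`.
* **Border handling.** Displaced samples outside the image contribute zero,
  with bilinear weights tapering linearly across a one-pixel border band —
  the natural continuation of zero-padded convolution. Offsets are not
  magnitude-capped.
* **Channel ordering.** Offset channels are interleaved (vertical,
  horizontal) per kernel point, kernel points in row-major order; offsets
  are shared across input channels and distinct per spatial location.

The compiled forward/backward kernels are verified in the test suite against
an independent nested-loop reference (`deformable_conv2d_reference()`) and
against central-difference gradients at non-lattice offsets; at exact
lattice points bilinear interpolation is only one-sided differentiable, which
is why gradient checks probe fractional offsets.

## Architecture

`build_dunet()` assembles a classical U-Net: per resolution level a block of
`conv_count` convolution units (each convolution → batch normalization →
ReLU), 2×2 max-pool downsampling, learned upsampling (2×2 stride-2
transposed convolution by default, nearest-neighbor + convolution as an
option), and channel-concatenation skip connections. In the default
specification the blocks of levels 2 and 3 — in the encoder *and* in the
counterpart decoder levels — are deformable: each unit gains a convolutional
offset layer feeding a deformable convolution. That places exactly four
deformable blocks. `deformable_levels = integer(0)` gives the plain U-Net
baseline, and because offset layers are zero-initialized a freshly built
deformable model is *bitwise* a U-Net until training moves the offsets.

The full-scale default is 5 levels with 32 base channels doubling per level;
the tests and the phantom study use a small 3-level, 8-channel variant. The
head is a 1×1 convolution with a sigmoid, so the output is a probability map
of the input's spatial size; binarization uses a strict `> 0.5` rule (a map
exactly at ½ yields an empty mask).

### Initialization for short training budgets

The reference training protocol (Adam, learning rate $10^{-4}$, 10 epochs)
was designed for cohorts of tens of thousands of slices. At phantom scale a
run sees only ~10³ optimizer steps, and since Adam's per-parameter step is
bounded by the learning rate, the reachable set of weights is a small ball
around the initialization. Three initialization choices, documented here as
deliberate design decisions, make the network trainable inside that ball
without touching the protocol itself:

* **Conservative convolution scale.** Convolutions feeding a batch norm are
  initialized at one tenth of the He scale. Batch normalization makes the
  forward pass invariant to the weight norm, while the *angular* movement
  per step grows as the norm shrinks, so features can reorient quickly; the
  variance guard of batch norm (`eps = 1e-5`) remains orders of magnitude
  below the pre-normalization variances this produces.
* **DC-free filters.** Each 3×3 tap is projected onto the zero-sum subspace
  at initialization, so first features are local-contrast detectors —
  insensitive to the slowly varying background level that dominates
  windowed CT. The mean component stays learnable.
* **High-recall head.** The head starts with zero weights and a positive
  bias (+0.5 logit). Under the size-weighted Dice losses the dominant
  background class is driven below threshold quickly (its logits move
  through the scale-free feature pathway), whereas the scarce foreground
  drifts upward slowly; starting above threshold means the foreground must
  only be *maintained*, not recovered. This mirrors the classification-prior
  head-bias initialization common in dense detection, adapted to the
  opposite (recall-first) operating point that Dice-family training favors.
  Relatedly, interior batch-norm scales start at 15, which sets the ratio
  between feature magnitude and the head's bounded per-step movement.

Batch-norm statistics are per channel over (height, width, batch); training
mode uses biased batch variance and updates running statistics with momentum
0.1; evaluation mode is deterministic.

## Loss family

Three Dice-family losses operate on the predicted probabilities $p_i \in
[0,1]$ and binary truth $g_i$; the two-class construction derives the
background channel as the elementwise complement, which is forced by the
$(1-p)(1-g)$ structure of the two-sided Dice loss.

* `dice_loss()` — the two-sided soft Dice loss
  $1-\frac{\sum p g+\epsilon}{\sum(p+g)+\epsilon}
     -\frac{\sum(1-p)(1-g)+\epsilon}{\sum(2-p-g)+\epsilon}$,
  implemented exactly in this form (each one-sided ratio saturates near ½;
  no conventional factor 2), since this is the baseline the loss comparison
  is defined against.
* `generalized_dice_loss()` — the two-class generalized Dice loss with
  weights $w_l$ inversely related to class size. The printed definition uses
  the *linear* weighting $w_l = 1/\sum_i g_{li}$, while the original
  generalized-Dice reference squares the denominator; linear is the default
  here and `weighting = "squared"` switches. The cross-class denominator is
  strictly positive for non-empty inputs, so no smoothing constant is
  needed; an empty class receives weight $1/10^{-5}$ and the loss stays
  finite.
* `focal_generalized_dice_loss()` — per-class generalized-Dice complements
  raised to $1/\gamma$ and summed,
  $\sum_{l=1}^{2}\left[1-\frac{2 w_l \sum_i p_{li} g_{li}+\epsilon}
  {w_l \sum_i (p_{li}+g_{li})+\epsilon}\right]^{1/\gamma}$, $\gamma=4/3$ by
  default (valid range $[1,3]$). Because $2\sum pg \le \sum(p+g)$, each
  bracket lies in $[0,1]$ analytically; it is clamped there defensively
  before the fractional power. Note that $w_l$ appears in both numerator and
  denominator of the per-class ratio, so away from the $\epsilon$ terms it
  cancels analytically; the formula is implemented as defined rather than
  "fixed", and the cancellation is simply documented here.

Gradients are hand-derived for all three losses (the training loop consumes
`seg_loss()`, which returns value and elementwise gradient). The derivative
of $b^{1/\gamma}$ diverges as a bracket $b \to 0$ for $\gamma > 1$; the
gradient path clamps $b \ge 10^{-7}$, so gradients are finite even at a
perfect prediction. Default $\epsilon = 10^{-5}$ everywhere.

## Metrics

`dsc()`, `precision()`, `recall()` and `f_measure()` operate on congruent
binary voxel sets, computed per volume in 3D (predicted slices are stacked
before scoring, matching the volumetric-overlap reading of the metrics). One
printed definition required a correction: the recall formula as printed
duplicates the precision denominator $|V_{seg}|$; it is implemented with the
$|V_{gt}|$ denominator its stated meaning ("positives correctly identified")
requires. For strictly binary masks the F-measure is algebraically identical
to DSC — the suite asserts this to $10^{-12}$ on a thousand random pairs —
which is why a cohort can meaningfully report both. Empty-mask corner cases
are made total (both-empty → 1, one-empty → 0) and warn when triggered.
`cohort_summary()` aggregates per-case metrics into mean/SD/min/max of DSC
and means of the rest; the SD is the sample SD by default (population SD
available), a convention the aggregation records explicitly because cohort
tables in the field rarely state it.

## Semiautomated preprocessing

CT intensities are windowed to $[-100, 240]$ HU — soft tissue plus margin —
and mapped linearly to $[0,1]$ (`truncate_and_normalize()`); the window maps
−500 → 0, 70 → 0.5, 240 → 1 exactly. Localization follows the semiautomated
workflow: during training the per-volume bounding box comes from the mask's
coordinate extremes; at inference it comes from a user-supplied CSV of
per-slice extremes (`roi_for_case()` pools them into one per-volume box so
the crop window is temporally stable across slices — a per-slice window
would make the cropped anatomy jitter). Boxes are 0-based, half-open,
expanded by a 16-pixel default margin and clamped. `crop_to_shape()` takes
every slice to exactly 192 × 256 (rows × cols at full scale; the phantom
study uses 64 × 64), centered on the box and shifted inward at borders;
undersized images are zero-padded symmetrically. The transform is recorded
so predictions are re-embedded into the original geometry
(`uncrop_volume()`). No resampling to uniform voxel spacing is performed.
Cross-validation uses seeded, case-disjoint folds whose sizes differ by at
most one — 82 cases at $k=4$ give 21/21/20/20.

## The phantom generator

`generate_phantom_volume()` produces the study conditions every pipeline
stage is tested under: a 64 × 64 × 16 volume whose background is a
low-frequency Gaussian random field scaled into the soft-tissue range
(mean 50 HU, SD 20 HU, slice-correlated), carrying an elongated elliptical
target (axis ratio 3, per-slice area ≈ 0.6% of the slice, varying ±15%)
whose center drifts ≤ 2 px and whose orientation drifts ≤ 0.15 rad per
slice; the target sits 60 HU above the local background, two compact
distractor blobs sit 30 HU above background outside the mask, and white
Gaussian noise (SD 15 HU) covers everything. The mask marks exactly the
target. Generation is bit-reproducible under the seed.

These defaults mimic what makes the pancreas hard — sub-percent area,
elongated drifting shape, low contrast against textured background,
confusable neighbors — and were chosen once, on that reasoning. What the
phantoms do *not* emulate: anatomical context (named organs, bone, air),
partial-volume effects, scanner noise correlation, and the 100-fold larger
slice grids of real CT. Passing the phantom study therefore demonstrates
that the operator, network, losses and pipeline are implemented correctly
and can learn a pancreas-like target from scratch on a CPU; it does not
certify clinical performance.

## The phantom study and its problem sizes

The end-to-end study (also run by `scripts/acceptance.R`) trains the small
DUNet (3 levels, base 8, deformable levels {2, 3}; ~93k parameters) with the
focal generalized Dice loss (γ = 4/3) and Adam at learning rate $10^{-4}$
for 10 epochs on the 128 slices of 8 phantom volumes, using batch size 1 —
with so few slices, smaller batches buy proportionally more optimizer steps,
which under Adam's bounded per-step movement is the better trade. Held-out
phantom volumes are scored in 3D; a zero-contrast twin cohort serves as the
negative control (its DSC collapses toward zero because no signal links
image to mask). These problem sizes — 8 + 4 volumes of 16 slices at 64² —
are the package's chosen desk-scale study; the architecture and pipeline
run unchanged at full CT scale.

## Known limitations

* Training is single-threaded CPU R + compiled kernels; full-scale CT
  training is out of reach (and out of scope) — the full-scale architecture
  is provided and tested for contracts (shapes, block placement), not for
  accuracy.
* The parameter count of the published full-scale DUNet (~6.4 M) is not
  exactly reproducible because the channel widths behind it are not public;
  the default here uses classical U-Net widths (32 doubling per level) and
  `count_parameters()` reports whatever a given specification yields.
* Only binary (foreground/background) segmentation is supported; the loss
  family is two-class by construction.
* Offsets are unconstrained; very large learned offsets sample zeros
  outside the image, which is the documented border policy, not an error.
* The desk-scale training budget (~10³ optimizer steps at the reference
  learning rate) is marginal: on some phantom cohorts the network does not
  escape the high-recall starting regime within 10 epochs and the held-out
  DSC collapses. The phantom study is therefore seeded; at full data scale
  the budget argument disappears (the reference protocol takes ~20× more
  steps per epoch).
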