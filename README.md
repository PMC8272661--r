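# dunet

Semiautomated pancreas segmentation in abdominal CT with a **deformable
U-Net (DUNet)**, implemented from first principles in R.

The pancreas occupies well under 1% of a CT slice, has weak soft-tissue
contrast, and varies strongly in shape and position across patients. This
package implements the complete method stack for the slice-wise,
coarse-to-fine workflow used for that problem:

* **Deformable 2D convolution** with learned per-pixel, per-kernel-point
  sampling offsets and bilinear interpolation,
  $Y(p_0)=\sum_{p_n\in\mathcal{G}} W(p_n)\,X(p_0+p_n+\Delta p_n(p_0))$,
  with forward *and* hand-derived backward passes in compiled code
  (`standard_conv2d()`, `deformable_conv2d()`, `conv_offset_layer()`,
  `bilinear_sample()`, plus a brute-force reference oracle).
* **The DUNet architecture**: an encoder–decoder with skip connections in
  which the convolution blocks of resolution levels 2 and 3 (encoder and
  decoder) are deformable — exactly four deformable blocks in the default
  spec; `deformable_levels = integer(0)` gives the plain U-Net baseline
  (`dunet_spec()`, `build_dunet()`, `dunet_forward()`).
* **Dice-family losses for extreme class imbalance**: the two-sided soft
  Dice loss, the generalized Dice loss with size-balancing class weights
  $w_l$, and the **focal generalized Dice loss**
  $\mathrm{FGDL}=\sum_{l=1}^{2}\bigl[1-\tfrac{2 w_l \sum_i p_{li} g_{li}+\epsilon}
  {w_l \sum_i (p_{li}+g_{li})+\epsilon}\bigr]^{1/\gamma}$ with $\gamma=4/3$,
  all with analytic gradients (`dice_loss()`, `generalized_dice_loss()`,
  `focal_generalized_dice_loss()`, `seg_loss()`).
* **Volumetric metrics** — DSC, precision, recall, F-measure — and cohort
  aggregation with mean ± SD / min / max reporting (`dsc()`,
  `cohort_summary()`, tidy/glance/autoplot methods).
* **Semiautomated preprocessing**: Hounsfield-unit windowing to
  $[-100,240]$ HU and normalization to $[0,1]$, bounding boxes from
  annotated coordinate extremes, fixed-shape cropping (192 × 256 at full
  scale) with exact inverse re-embedding, and seeded case-disjoint k-fold
  splits (`truncate_and_normalize()`, `roi_from_annotations()`,
  `crop_to_shape()`, `make_folds()`).
* **A seeded phantom generator** producing pancreas-like targets —
  elongated, drifting, low-contrast blobs on textured backgrounds with
  distractors — so the whole pipeline trains and evaluates on one CPU with
  no external data (`phantom_config()`, `generate_phantom_volume()`,
  `generate_cohort()`).
* **Training, prediction, evaluation, cross-validation** with Adam
  (`train_dunet()`, `predict_volume()`, `evaluate_predictions()`,
  `cross_validate()`), plus a command-line interface
  (`inst/cli/dunet.R` with `phantom`/`train`/`predict`/`evaluate`/`crossval`
  subcommands).

NIfTI volumes are read and written via RNifti, PNG slice stacks via png,
configs via yaml, reports as CSV + JSON.

## Worked example

Train the small DUNet on eight 64×64 phantom volumes and score two held-out
volumes (≈4 minutes on one CPU):

```r
library(dunet)

cfg <- phantom_config(seed = 1)              # 64x64x16, +60 HU target, 15 HU noise
config <- run_config(
  model = dunet_spec(levels = 3, base_channels = 8, deformable_levels = c(2, 3)),
  loss  = loss_config("focal_generalized_dice", gamma = 4/3),
  lr = 1e-4, batch_size = 1, epochs = 10, crop = c(64, 64), seed = 1)

samples <- list()
for (i in 1:8) {
  ph <- generate_phantom_volume(cfg, index = i)
  samples <- c(samples, prepare_slices(ph$image, ph$mask, config))
}
fit <- train_dunet(samples, config)

preds <- list(); gts <- list()
for (i in 9:10) {
  ph <- generate_phantom_volume(cfg, index = i)
  roi <- roi_from_annotations(ph$mask, margin = config$roi_margin)
  preds[[ph$image$id]] <- predict_volume(fit, ph$image, roi, config)
  gts[[ph$mask$id]] <- ph$mask
}
evaluate_predictions(preds, gts)
#> <cohort_report> 2 cases: DSC 0.9384 +/- 0.0255 (min 0.9204, max 0.9564)
```

The report says the trained network recovers the phantom "pancreas" with a
mean Dice overlap of about 0.94 on volumes it never saw — the target is
found, its elongated shape is traced, and the similar-intensity distractors
are rejected. A zero-contrast control cohort (set `contrast_delta = 0`)
trained identically collapses to DSC 0, confirming the score is earned
from image evidence rather than mask geometry.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/dunet.R phantom --outdir data --n-train 8 --n-test 2 --seed 1
Rscript inst/cli/dunet.R train   --data data --outdir run --epochs 10 --batch 1
Rscript inst/cli/dunet.R predict --checkpoint run/checkpoints/model.rds \
    --volume data/test/phantom_009_image.nii.gz --roi data/rois.csv --out pred.nii.gz
Rscript inst/cli/dunet.R evaluate --pred-dir preds --gt-dir data/test --outdir report
```

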