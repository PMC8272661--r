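test_that("training runs, logs per-epoch losses, and aborts on empty data", {
  tp <- tiny_phantom_samples(n_volumes = 1, seed = 31)
  config <- tp$config
  fit <- train_dunet(tp$samples, config)
  expect_s3_class(fit, "dunet_fit")
  expect_equal(nrow(fit$log), config$epochs)
  expect_true(all(is.finite(fit$log$loss)))
  expect_error(train_dunet(list(), config), "empty dataset")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$epochs, config$epochs)
})

test_that("training is deterministic under the seed and continues from checkpoints", {
  tp <- tiny_phantom_samples(n_volumes = 1, seed = 32)
  f1 <- train_dunet(tp$samples, tp$config)
  f2 <- train_dunet(tp$samples, tp$config)
  expect_identical(f1$log, f2$log)
  # a reloaded checkpoint reproduces its predictions exactly
  path <- tempfile(fileext = ".rds")
  save_checkpoint(f1$model, path, config = tp$config)
  ck <- load_checkpoint(path)
  x <- array(runif(32 * 32), c(1, 32, 32))
  expect_identical(dunet_forward(ck$model, x), dunet_forward(f1$model, x))
})

test_that("loss decreases over training on a learnable phantom set", {
  tp <- tiny_phantom_samples(n_volumes = 2, seed = 33)
  config <- tp$config
  config$epochs <- 5L
  config$lr <- 3e-3
  fit <- train_dunet(tp$samples, config)
  expect_lt(fit$log$loss[5], fit$log$loss[1])
})

test_that("prediction re-embeds the cropped mask into the original geometry", {
  tp <- tiny_phantom_samples(n_volumes = 1, seed = 34)
  cfg <- tp$cfg
  ph <- generate_phantom_volume(cfg)
  fit <- train_dunet(tp$samples, tp$config)
  roi <- roi_from_annotations(ph$mask, margin = tp$config$roi_margin)
  pred <- predict_volume(fit, ph$image, roi, tp$config)
  expect_s3_class(pred, "mask_volume")
  expect_equal(dim(pred$data), dim(ph$image$data))
  expect_true(all(pred$data %in% c(0, 1)))
  # missing ROI falls back to the whole volume with a warning
  expect_warning(predict_volume(fit, ph$image, NULL, tp$config), "whole-volume")
})

test_that("thresholding is strictly greater-than at 0.5", {
  # a probability map identically 0.5 must binarize to all background
  p <- array(0.5, c(4, 4))
  expect_true(all((p > 0.5) * 1 == 0))
  # predict_volume applies the same rule: a model whose head is fully
  # zeroed emits exactly 0.5 everywhere -> empty mask under strict >
  m <- build_dunet(dunet_spec(levels = 2, base_channels = 4), seed = 1)
  m$out$b[] <- 0
  cfg <- run_config(model = dunet_spec(levels = 2, base_channels = 4),
                    crop = c(32L, 32L))
  img <- image_volume(array(0, c(2, 32, 32)), id = "flat")
  pred <- suppressWarnings(predict_volume(m, img, NULL, cfg))
  expect_equal(sum(pred$data), 0)
})

test_that("evaluation pairs cases by id and reports mismatches explicitly", {
  gt <- list(a = rand_mask(c(2, 4, 4), 0.5), b = rand_mask(c(2, 4, 4), 0.5))
  expect_error(evaluate_predictions(list(a = gt$a), gt), "without a counterpart.*b")
  rep <- evaluate_predictions(gt, gt)
  expect_equal(rep$summary$dsc_mean, 1)
  expect_equal(rep$summary$dsc_sd, 0)
  # one corrupted (all-zero) prediction drags min and mean down
  preds <- gt; preds$b <- preds$b * 0
  rep2 <- suppressWarnings(evaluate_predictions(preds, gt))
  expect_equal(rep2$summary$dsc_min, 0)
  expect_equal(rep2$summary$dsc_mean, 0.5)
  # discovery order does not matter
  rep3 <- suppressWarnings(evaluate_predictions(rev(preds), gt))
  expect_equal(rep3$summary, rep2$summary)
})

test_that("cross-validation scores every case exactly once with the seeded folds", {
  cfg <- phantom_config(image_size = c(32, 32), slices_per_volume = 2,
                        target_area_fraction = 0.008, seed = 36)
  images <- list(); masks <- list()
  for (i in 1:4) {
    ph <- generate_phantom_volume(cfg, index = i)
    images[[ph$image$id]] <- ph$image
    masks[[ph$mask$id]] <- ph$mask
  }
  config <- run_config(model = dunet_spec(levels = 2L, base_channels = 2L,
                                          deformable_levels = 2L),
                       crop = c(32L, 32L), epochs = 1L, batch_size = 4L,
                       folds = 4L, seed = 9)
  cv <- cross_validate(images, masks, config)
  expect_equal(nrow(cv$report$per_case), 4)
  expect_setequal(cv$report$per_case$case_id, names(images))
  expect_equal(anyDuplicated(cv$report$per_case$case_id), 0L)
  expect_equal(cv$report$summary$dsc_mean, mean(cv$report$per_case$dsc))
  # fold labels in the report match the seeded assignment
  folds <- make_folds(names(images), k = 4, seed = 9)
  expect_equal(cv$report$per_case$fold,
               folds$fold[match(cv$report$per_case$case_id, folds$case_id)])
})

test_that("run configs round-trip through YAML", {
  config <- run_config(model = dunet_spec(levels = 3L, base_channels = 8L,
                                          deformable_levels = c(2L, 3L)),
                       loss = loss_config("generalized_dice", epsilon = 1e-4,
                                          gamma = 2, weighting = "squared"),
                       lr = 5e-4, batch_size = 3L, epochs = 7L, seed = 42L,
                       crop = c(64L, 64L))
  path <- tempfile(fileext = ".yaml")
  write_run_config(config, path)
  back <- read_run_config(path)
  expect_equal(back$model$levels, 3L)
  expect_equal(back$model$deformable_levels, c(2L, 3L))
  expect_equal(back$loss$kind, "generalized_dice")
  expect_equal(back$loss$weighting, "squared")
  expect_equal(back$lr, 5e-4)
  expect_equal(back$crop, c(64L, 64L))
})

test_that("the CLI wires phantom generation, training, prediction and evaluation together", {
  td <- tempfile(); dir.create(td)
  data_dir <- file.path(td, "data"); out_dir <- file.path(td, "run")
  expect_equal(dunet_cli(c("phantom", "--outdir", data_dir, "--size", "32",
                           "--slices", "2", "--n-train", "2", "--n-test", "1",
                           "--seed", "5")), 0L)
  expect_true(file.exists(file.path(data_dir, "rois.csv")))
  st <- dunet_cli(c("train", "--data", data_dir, "--outdir", out_dir,
                    "--epochs", "1", "--crop-rows", "32", "--crop-cols", "32"))
  expect_equal(st, 0L)
  ckpt <- file.path(out_dir, "checkpoints", "model.rds")
  expect_true(file.exists(ckpt))
  log <- utils::read.csv(file.path(out_dir, "logs", "training_log.csv"))
  expect_equal(nrow(log), 1)
  expect_true(file.exists(file.path(out_dir, "config.yaml")))
  # predict the test volume and evaluate against its ground truth
  test_img <- list.files(file.path(data_dir, "test"), pattern = "image",
                         full.names = TRUE)[1]
  pred_dir <- file.path(td, "preds"); dir.create(pred_dir)
  id <- sub("_image\\.nii\\.gz$", "", basename(test_img))
  st2 <- dunet_cli(c("predict", "--checkpoint", ckpt, "--volume", test_img,
                     "--roi", file.path(data_dir, "rois.csv"),
                     "--out", file.path(pred_dir, paste0(id, "_mask.nii.gz"))))
  expect_equal(st2, 0L)
  st3 <- dunet_cli(c("evaluate", "--pred-dir", pred_dir,
                     "--gt-dir", file.path(data_dir, "test"),
                     "--outdir", file.path(td, "report")))
  expect_equal(st3, 0L)
  expect_true(file.exists(file.path(td, "report", "summary.json")))
  # errors surface as nonzero status with a one-line diagnostic
  expect_message(st4 <- dunet_cli(c("train", "--data", tempfile(),
                                    "--outdir", out_dir)), "error")
  expect_equal(st4, 1L)
  expect_equal(suppressMessages(dunet_cli(c("nonsense"))), 1L)
})
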