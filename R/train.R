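#' Run configuration
#'
#' Bundles the architecture spec, loss configuration, optimizer settings and
#' preprocessing keys of a training or cross-validation run. Defaults follow
#' the reference training protocol: Adam, learning rate 0.0001, batch size
#' 6, 10 epochs. The resolved configuration is fully serializable and is
#' written next to a run's outputs.
#'
#' @param model A [dunet_spec()].
#' @param loss A [loss_config()].
#' @param lr Adam learning rate. Default 0.0001.
#' @param batch_size Slices per batch. Default 6.
#' @param epochs Training epochs. Default 10.
#' @param seed Master seed; fans out to weight init, shuffling and fold
#'   assignment.
#' @param window HU window `(lo, hi)`. Default `c(-100, 240)`.
#' @param crop Cropped slice shape `(rows, cols)`. Default `c(192, 256)`.
#' @param roi_margin ROI expansion margin in pixels. Default 16.
#' @param threshold Binarization threshold on the probability map (strictly
#'   greater-than). Default 0.5.
#' @param folds Fold count for cross-validation. Default 4.
#' @return A `run_config` object.
#' @export
run_config <- function(model = dunet_spec(), loss = loss_config(),
                       lr = 1e-4, batch_size = 6L, epochs = 10L, seed = 1L,
                       window = c(-100, 240), crop = c(192L, 256L),
                       roi_margin = 16L, threshold = 0.5, folds = 4L) {
  structure(list(model = model, loss = loss, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 window = window, crop = as.integer(crop),
                 roi_margin = as.integer(roi_margin), threshold = threshold,
                 folds = as.integer(folds)),
            class = "run_config")
}

#' Serialize / restore a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- do.call(dunet_spec, y$model[c("levels", "base_channels",
                                        "channel_multipliers",
                                        "deformable_levels", "upsample_mode",
                                        "conv_count", "in_channels")])
  lcfg <- do.call(loss_config, y$loss[c("kind", "epsilon", "gamma", "weighting")])
  run_config(model = spec, loss = lcfg, lr = y$lr, batch_size = y$batch_size,
             epochs = y$epochs, seed = y$seed, window = y$window,
             crop = y$crop, roi_margin = y$roi_margin,
             threshold = y$threshold, folds = y$folds)
}

#' Preprocess a volume into training slices
#'
#' The semiautomated pipeline: HU windowing + normalization, per-volume ROI
#' from the mask coordinate extremes (training mode), identical crop of
#' image and mask to the configured slice shape, then splitting into 2D
#' samples. Slices without foreground are retained so the background class
#' is trained too.
#'
#' @param image An `image_volume` (HU).
#' @param mask The congruent `mask_volume`.
#' @param config A [run_config()].
#' @return List of samples, each `list(x, y)` with `x` a normalized
#'   `(rows, cols)` matrix and `y` the binary mask slice.
#' @export
prepare_slices <- function(image, mask, config = run_config()) {
  img <- truncate_and_normalize(image, config$window[1], config$window[2])
  box <- roi_from_annotations(mask, margin = config$roi_margin)
  ci <- crop_to_shape(img, box, target = config$crop)
  cm <- crop_to_shape(mask, box, target = config$crop)
  lapply(seq_len(dim(ci$data)[1]), function(s)
    list(x = ci$data[s, , ], y = cm$data[s, , ]))
}

stack_batch <- function(samples, idx) {
  H <- nrow(samples[[idx[1]]]$x); W <- ncol(samples[[idx[1]]]$x)
  x <- array(0, dim = c(1L, H, W, length(idx)))
  g <- array(0, dim = c(1L, H, W, length(idx)))
  for (j in seq_along(idx)) {
    x[1, , , j] <- samples[[idx[j]]]$x
    g[1, , , j] <- samples[[idx[j]]]$y
  }
  list(x = x, g = g)
}

#' Train a deformable U-Net
#'
#' Mini-batch Adam training on 2D slices with the configured Dice-family
#' loss. The loss gradient is hand-derived and propagated through the
#' sigmoid head, decoder, skip connections, deformable and standard blocks
#' down to every weight, bias, offset layer and batch-norm parameter.
#' Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param samples List of `list(x, y)` training slices (see
#'   [prepare_slices()]).
#' @param config A [run_config()].
#' @param model Optional pre-built or checkpointed `dunet_model` to continue
#'   training; by default a fresh model is initialized from
#'   `config$model` with a seed derived from `config$seed`.
#' @param verbose Print per-epoch loss.
#' @return A `dunet_fit`: list with `model`, `log` (tibble: epoch, loss) and
#'   `config`.
#' @export
train_dunet <- function(samples, config = run_config(), model = NULL,
                        verbose = FALSE) {
  if (length(samples) == 0) stop("empty dataset")
  if (is.null(model)) model <- build_dunet(config$model, seed = config$seed + 1L)
  params <- model_params(model)
  opt <- adam_init(params)
  n <- length(samples)
  bs <- min(config$batch_size, n)
  log_rows <- vector("list", config$epochs)
  with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      total <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        b <- stack_batch(samples, idx)
        fw <- dunet_forward_full(model, b$x, train = TRUE)
        model <- fw$model
        l <- seg_loss(fw$p, b$g, config$loss)
        if (!is.finite(l$value))
          stop("training aborted: non-finite loss at epoch ", epoch)
        bw <- dunet_backward(model, fw$caches, l$grad, fw$p)
        st <- adam_step(params, bw$grads_flat, opt, lr = config$lr)
        params <- st$params; opt <- st$state
        model <- model_set_params(model, params)
        total <- total + l$value; nb <- nb + 1L
      }
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch, loss = total / nb)
      if (verbose) message(sprintf("epoch %d: loss %.5f", epoch, total / nb))
    }
  })
  structure(list(model = model, log = do.call(rbind, log_rows),
                 config = config),
            class = "dunet_fit")
}

#' @export
print.dunet_fit <- function(x, ...) {
  cat("<dunet_fit> ", nrow(x$log), " epochs, final loss ",
      signif(x$log$loss[nrow(x$log)], 5), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.cohort_report
#' @exportS3Method generics::tidy
tidy.dunet_fit <- function(x, ...) x$log

#' @rdname tidy.cohort_report
#' @exportS3Method generics::glance
glance.dunet_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log),
                 final_loss = x$log$loss[nrow(x$log)],
                 parameters = count_parameters(x$model))
}

#' Plot the training loss curve
#'
#' @param object A `dunet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dunet_fit <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' Predict a segmentation mask for a volume
#'
#' The semiautomated inference path: window-normalize, crop around the
#' supplied ROI (user-annotated coordinate extremes; falls back to the whole
#' volume with a warning if none is given), run the network slice-wise in
#' evaluation mode, threshold the probability map (strictly greater than
#' `config$threshold`), and re-embed the result into the original volume
#' geometry.
#'
#' @param fit A `dunet_fit` (or a bare `dunet_model`).
#' @param image An `image_volume` in HU.
#' @param roi A `roi_box`, or `NULL` for the whole-volume fallback.
#' @param config A [run_config()]; defaults to the fit's own.
#' @return A `mask_volume` with the input volume's geometry.
#' @export
predict_volume <- function(fit, image, roi = NULL, config = NULL) {
  model <- if (inherits(fit, "dunet_fit")) fit$model else fit
  if (is.null(config))
    config <- if (inherits(fit, "dunet_fit")) fit$config else run_config()
  d <- dim(image$data)
  if (is.null(roi)) {
    warning("no ROI supplied for case '", image$id,
            "'; falling back to the whole-volume box")
    roi <- roi_box(0L, d[2], 0L, d[3])
  }
  img <- truncate_and_normalize(image, config$window[1], config$window[2])
  ci <- crop_to_shape(img, roi, target = config$crop)
  win <- attr(ci, "crop_window")
  n <- d[1]
  x <- array(0, dim = c(1L, config$crop[1], config$crop[2], n))
  for (s in seq_len(n)) x[1, , , s] <- ci$data[s, , ]
  p <- dunet_forward(model, x, train = FALSE)
  pred <- array(0, dim = c(n, config$crop[1], config$crop[2]))
  for (s in seq_len(n)) pred[s, , ] <- (p[1, , , s] > config$threshold) * 1
  full <- uncrop_volume(pred, win)
  mask_volume(full, spacing = image$spacing, id = image$id)
}

#' Evaluate predictions against ground truth
#'
#' Pairs predicted and ground-truth mask volumes by case id and computes the
#' cohort report (metrics in 3D per volume). Ids present on one side only
#' are an error, listed explicitly.
#'
#' @param pred_masks Named list of predicted `mask_volume`s (or arrays).
#' @param gt_masks Named list of ground-truth masks.
#' @param sd_type Passed to [cohort_summary()].
#' @return A `cohort_report`.
#' @export
evaluate_predictions <- function(pred_masks, gt_masks, sd_type = "sample") {
  pids <- names(pred_masks); gids <- names(gt_masks)
  miss <- union(setdiff(pids, gids), setdiff(gids, pids))
  if (length(miss))
    stop("case ids without a counterpart: ", paste(sort(miss), collapse = ", "))
  gids <- sort(gids)
  cohort_summary(
    gt_masks = lapply(stats::setNames(gids, gids),
                      function(i) vol_data(gt_masks[[i]])),
    seg_masks = lapply(stats::setNames(gids, gids),
                       function(i) vol_data(pred_masks[[i]])),
    sd_type = sd_type)
}

#' k-fold cross-validation on a set of volumes
#'
#' Splits cases into `config$folds` case-disjoint folds, trains one model
#' per fold on the remaining cases and predicts the held-out fold, then
#' pools the per-case metrics into a single cohort report in which every
#' case is scored exactly once.
#'
#' @param images Named list of `image_volume`s (names are case ids).
#' @param masks Named list of congruent `mask_volume`s.
#' @param config A [run_config()].
#' @param verbose Print fold progress.
#' @return List with `report` (pooled `cohort_report`), `folds` (the fold
#'   tibble) and `fits` (per-fold `dunet_fit`s).
#' @export
cross_validate <- function(images, masks, config = run_config(),
                           verbose = FALSE) {
  ids <- names(images)
  if (is.null(ids) || !identical(sort(ids), sort(names(masks))))
    stop("images and masks must be named lists with matching case ids")
  folds <- make_folds(ids, k = config$folds, seed = config$seed)
  preds <- list()
  fits <- list()
  for (f in seq_len(config$folds)) {
    train_ids <- folds$case_id[folds$fold != f]
    test_ids <- folds$case_id[folds$fold == f]
    samples <- unlist(lapply(train_ids, function(i)
      prepare_slices(images[[i]], masks[[i]], config)), recursive = FALSE)
    fit <- train_dunet(samples, config)
    fits[[f]] <- fit
    for (i in test_ids) {
      roi <- roi_from_annotations(masks[[i]], margin = config$roi_margin)
      preds[[i]] <- predict_volume(fit, images[[i]], roi, config)
    }
    if (verbose) message("fold ", f, " done (", length(test_ids), " held out)")
  }
  report <- evaluate_predictions(preds, masks[names(preds)])
  report$per_case$fold <- folds$fold[match(report$per_case$case_id,
                                           folds$case_id)]
  list(report = report, folds = folds, fits = fits)
}
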