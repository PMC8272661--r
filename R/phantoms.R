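#' Configuration of the synthetic phantom generator
#'
#' Phantoms emulate the challenge the pancreas poses on CT: a small (well
#' under 1% of the slice area), elongated, smoothly deforming target with
#' modest intensity contrast, embedded in a textured soft-tissue background
#' with distractor structures of similar intensity. They exercise every
#' pipeline stage — HU windowing, ROI cropping, training, evaluation —
#' without any external data.
#'
#' @param image_size Slice shape `(H, W)`. Default `c(64, 64)`.
#' @param n_volumes Number of volumes a cohort draws. Default 8.
#' @param slices_per_volume Slices per volume. Default 16.
#' @param target_area_fraction Per-slice target area as a fraction of the
#'   slice; default 0.006 (the pancreas rarely exceeds 0.8%).
#' @param contrast_delta Target intensity above background, HU. Default 60.
#' @param noise_sd Additive Gaussian noise, HU. Default 15.
#' @param n_distractors Compact distractor blobs per volume at half the
#'   target contrast, never overlapping the target. Default 2.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bit-identically.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(image_size = c(64L, 64L), n_volumes = 8L,
                           slices_per_volume = 16L,
                           target_area_fraction = 0.006,
                           contrast_delta = 60, noise_sd = 15,
                           n_distractors = 2L, seed = 1L) {
  if (target_area_fraction <= 0.0005 || target_area_fraction >= 0.01)
    stop("target_area_fraction must lie in (0.0005, 0.01)")
  if (target_area_fraction * prod(image_size) < 4)
    stop("target_area_fraction infeasible for image_size: target below 4 pixels")
  structure(list(image_size = as.integer(image_size),
                 n_volumes = as.integer(n_volumes),
                 slices_per_volume = as.integer(slices_per_volume),
                 target_area_fraction = target_area_fraction,
                 contrast_delta = contrast_delta, noise_sd = noise_sd,
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Low-frequency Gaussian random field in soft-tissue HU range (~0-100),
# slice-correlated so the background evolves smoothly through the volume.
phantom_background <- function(H, W, n_slices, grid = 6L, rho = 0.9) {
  gy <- seq(0, H - 1, length.out = grid)
  gx <- seq(0, W - 1, length.out = grid)
  coarse <- matrix(stats::rnorm(grid * grid), grid, grid)
  bg <- array(0, dim = c(n_slices, H, W))
  yi <- findInterval(seq_len(H) - 1, gy, rightmost.closed = TRUE)
  xi <- findInterval(seq_len(W) - 1, gx, rightmost.closed = TRUE)
  interp <- function(cm) {
    # bilinear interpolation of the coarse grid onto the pixel grid
    out <- matrix(0, H, W)
    for (r in seq_len(H)) {
      i <- min(yi[r], grid - 1L)
      fy <- ((r - 1) - gy[i]) / (gy[i + 1] - gy[i])
      row <- (1 - fy) * cm[i, ] + fy * cm[i + 1, ]
      i2 <- pmin(xi, grid - 1L)
      fx <- ((seq_len(W) - 1) - gx[i2]) / (gx[i2 + 1] - gx[i2])
      out[r, ] <- (1 - fx) * row[i2] + fx * row[i2 + 1]
    }
    out
  }
  for (s in seq_len(n_slices)) {
    if (s > 1) coarse <- rho * coarse +
        sqrt(1 - rho^2) * matrix(stats::rnorm(grid * grid), grid, grid)
    bg[s, , ] <- interp(coarse)
  }
  50 + 20 * bg / max(stats::sd(bg), 1e-8)
}

ellipse_mask <- function(H, W, center, a, b, theta) {
  dy <- matrix(seq_len(H) - 1 - center[1], H, W)
  dx <- matrix(seq_len(W) - 1 - center[2], H, W, byrow = TRUE)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one phantom volume with its ground-truth mask
#'
#' The target is an elongated ellipse whose center, orientation and area
#' drift smoothly from slice to slice (center moves at most 2 px per slice),
#' drawn at `background + contrast_delta`; distractor blobs of half that
#' contrast are placed outside the mask; low-frequency background texture
#' and white Gaussian noise complete the slice. The mask marks exactly the
#' target. Deterministic given `cfg$seed` (plus `index` for cohort members).
#'
#' @param cfg A [phantom_config()].
#' @param index Volume index within a cohort (offsets the seed). Default 1.
#' @param id Case label.
#' @return List with `image` (an `image_volume`, HU), `mask`
#'   (a `mask_volume`) and `background` (the noise-free background array).
#' @export
generate_phantom_volume <- function(cfg, index = 1L,
                                    id = sprintf("phantom_%03d", index)) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  S <- cfg$slices_per_volume
  with_seed(cfg$seed + 7919L * (as.integer(index) - 1L), {
    bg <- phantom_background(H, W, S)
    mask <- array(0, dim = c(S, H, W))
    elong <- 3
    A0 <- cfg$target_area_fraction * H * W
    a0 <- sqrt(A0 * elong / pi)
    margin <- ceiling(a0) + 2
    center <- c(stats::runif(1, margin, H - margin),
                stats::runif(1, margin, W - margin))
    theta <- stats::runif(1, 0, pi)
    for (s in seq_len(S)) {
      A <- A0 * stats::runif(1, 0.85, 1.15)
      a <- sqrt(A * elong / pi); b <- sqrt(A / (elong * pi))
      m <- ellipse_mask(H, W, center, a, b, theta)
      if (!any(m)) m[round(center[1]) + 1, round(center[2]) + 1] <- TRUE
      mask[s, , ] <- m
      center <- pmin(pmax(center + stats::runif(2, -2, 2), margin), c(H, W) - margin)
      theta <- theta + stats::runif(1, -0.15, 0.15)
    }
    img <- bg + cfg$contrast_delta * mask
    if (cfg$n_distractors > 0) {
      for (d in seq_len(cfg$n_distractors)) {
        s0 <- sample.int(S, 1)
        span <- s0:min(S, s0 + 3L)
        dc <- c(stats::runif(1, 4, H - 4), stats::runif(1, 4, W - 4))
        r <- stats::runif(1, 1.5, 2.5)
        for (s in span) {
          dm <- ellipse_mask(H, W, dc, r, r, 0) & mask[s, , ] == 0
          img[s, , ][dm] <- img[s, , ][dm] + 0.5 * cfg$contrast_delta
        }
      }
    }
    if (cfg$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), sd = cfg$noise_sd), dim = dim(img))
    list(image = image_volume(img, id = id),
         mask = mask_volume(mask, id = id),
         background = bg)
  })
}

#' Generate a phantom cohort on disk
#'
#' Writes `n_train + n_test` phantom volumes and masks as NIfTI under
#' `dir/train` and `dir/test`, plus a single ROI CSV (`dir/rois.csv`)
#' derived from the mask coordinate extremes — the directory layout the
#' command-line interface consumes. Deterministic under `cfg$seed`.
#'
#' @param cfg A [phantom_config()].
#' @param n_train,n_test Number of training / test volumes.
#' @param dir Output directory.
#' @return A manifest tibble: `case_id`, `split`, `image`, `mask` paths.
#' @export
generate_cohort <- function(cfg, n_train, n_test, dir) {
  dir.create(file.path(dir, "train"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "test"), recursive = TRUE, showWarnings = FALSE)
  n <- n_train + n_test
  rois <- list()
  rows <- list()
  for (i in seq_len(n)) {
    split <- if (i <= n_train) "train" else "test"
    id <- sprintf("phantom_%03d", i)
    ph <- generate_phantom_volume(cfg, index = i, id = id)
    ip <- file.path(dir, split, paste0(id, "_image.nii.gz"))
    mp <- file.path(dir, split, paste0(id, "_mask.nii.gz"))
    write_volume(ph$image, ip)
    write_mask(ph$mask, mp)
    rois[[i]] <- roi_table_from_mask(ph$mask)
    rows[[i]] <- tibble::tibble(case_id = id, split = split,
                                image = ip, mask = mp)
  }
  write_roi_csv(do.call(rbind, rois), file.path(dir, "rois.csv"))
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
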