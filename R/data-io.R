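#' Image and mask volume containers
#'
#' Lightweight S3 containers for a 3D CT (or phantom) volume and its binary
#' mask. Intensities are stored as a `(slices, H, W)` array in Hounsfield
#' units before normalization; `spacing` is the voxel size in mm as
#' `(z, y, x)`.
#'
#' @param data 3D numeric array `(slices, H, W)`.
#' @param spacing Numeric length-3 voxel spacing `(z, y, x)` in mm.
#' @param id Case label.
#' @return An `image_volume` / `mask_volume` object.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), id = "case") {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) stop("volume data must be a 3D array")
  structure(list(data = data, spacing = as.numeric(spacing), id = id),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
mask_volume <- function(data, spacing = c(1, 1, 1), id = "case") {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) stop("mask data must be a 3D array")
  if (any(data != 0 & data != 1)) stop("mask must be binary")
  structure(list(data = data, spacing = as.numeric(spacing), id = id),
            class = "mask_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume '", x$id, "'> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = "/"),
      " mm, range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat("<mask_volume '", x$id, "'> ", paste(dim(x$data), collapse = "x"),
      " voxels, ", sum(x$data), " positive\n", sep = "")
  invisible(x)
}

vol_data <- function(v) if (inherits(v, c("image_volume", "mask_volume"))) v$data else v

#' Hounsfield-unit windowing and normalization
#'
#' Clips intensities to the window `[lo, hi]` (default `[-100, 240]` HU,
#' which retains soft tissue and discards irrelevant extremes) and then maps
#' the window linearly to `[0, 1]`: `(clip(v) - lo) / (hi - lo)`.
#'
#' @param vol An `image_volume` or bare array.
#' @param lo,hi Window bounds in HU; `lo < hi`.
#' @return Same type as the input, with values in `[0, 1]`.
#' @export
truncate_and_normalize <- function(vol, lo = -100, hi = 240) {
  if (lo >= hi) stop("window lower bound must be below upper bound")
  x <- vol_data(vol)
  y <- (pmin(pmax(x, lo), hi) - lo) / (hi - lo)
  if (length(unique(as.vector(y))) == 1L)
    warning("volume is constant after windowing")
  if (inherits(vol, "image_volume")) { vol$data <- y; vol } else y
}

#' ROI box from coordinate extremes
#'
#' The semiautomated localization step: the minimum and maximum row/column
#' coordinates of the pancreas (from a ground-truth mask during training, or
#' radiologist-annotated extremes at inference) define a tight bounding box,
#' expanded by a safety margin and clamped to the image bounds. Boxes use
#' 0-based, inclusive-min/exclusive-max coordinates.
#'
#' @param mask A `mask_volume`, 3D binary array, or 2D binary slice.
#' @param margin Expansion margin in pixels (default 16).
#' @return A `roi_box`: list with `min_row`, `max_row`, `min_col`, `max_col`.
#' @export
roi_from_annotations <- function(mask, margin = 16L) {
  m <- vol_data(mask)
  d <- dim(m)
  if (length(d) == 2L) { dim(m) <- c(1L, d); d <- dim(m) }
  pos <- which(m > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop("no pancreas annotation: mask has no positive voxel")
  H <- d[2]; W <- d[3]
  roi_box(min_row = max(0L, min(pos[, 2]) - 1L - margin),
          max_row = min(H, max(pos[, 2]) + margin),
          min_col = max(0L, min(pos[, 3]) - 1L - margin),
          max_col = min(W, max(pos[, 3]) + margin))
}

#' @rdname roi_from_annotations
#' @param min_row,max_row,min_col,max_col Box coordinates, 0-based,
#'   half-open.
#' @export
roi_box <- function(min_row, max_row, min_col, max_col) {
  if (min_row >= max_row || min_col >= max_col)
    stop("ROI box must satisfy min < max on both axes")
  structure(list(min_row = as.integer(min_row), max_row = as.integer(max_row),
                 min_col = as.integer(min_col), max_col = as.integer(max_col)),
            class = "roi_box")
}

# Compute the crop window: target-sized, centered on the box center, shifted
# inward at borders; if the image is smaller than the target on an axis the
# window extends beyond the image and is zero-padded.
crop_window <- function(box, img_dims, target = c(192L, 256L)) {
  place <- function(lo, hi, size, tgt) {
    center <- (lo + hi) / 2
    start <- round(center - tgt / 2)
    if (tgt >= size) {
      # symmetric padding for undersized images
      start <- -((tgt - size) %/% 2)
    } else {
      start <- max(0L, min(start, size - tgt))
    }
    c(start, start + tgt)   # half-open, may extend outside [0, size)
  }
  r <- place(box$min_row, box$max_row, img_dims[1], target[1])
  cc <- place(box$min_col, box$max_col, img_dims[2], target[2])
  list(rows = r, cols = cc, target = as.integer(target),
       img_dims = as.integer(img_dims))
}

extract_window <- function(slice, win) {
  tgt <- win$target
  out <- matrix(0, tgt[1], tgt[2])
  H <- nrow(slice); W <- ncol(slice)
  r0 <- max(win$rows[1], 0L); r1 <- min(win$rows[2], H)
  c0 <- max(win$cols[1], 0L); c1 <- min(win$cols[2], W)
  if (r1 > r0 && c1 > c0)
    out[(r0 - win$rows[1] + 1):(r1 - win$rows[1]),
        (c0 - win$cols[1] + 1):(c1 - win$cols[1])] <-
      slice[(r0 + 1):r1, (c0 + 1):c1]
  out
}

#' Crop a volume to a fixed slice shape around an ROI
#'
#' Every slice is cropped to exactly `target` (rows x cols, default
#' 192 x 256), centered on the ROI box center and shifted inward where the
#' window would cross the image border; images smaller than the target are
#' zero-padded symmetrically. Apply the identical call to the image and its
#' mask to keep them congruent. The applied window is attached as attribute
#' `"crop_window"` so predictions can be re-embedded with [uncrop_volume()].
#'
#' @param vol An `image_volume`, `mask_volume` or 3D array.
#' @param box A `roi_box` (one box per volume).
#' @param target Output slice shape `(rows, cols)`.
#' @return Same type as input with slices of shape `target`.
#' @export
crop_to_shape <- function(vol, box, target = c(192L, 256L)) {
  x <- vol_data(vol)
  d <- dim(x)
  win <- crop_window(box, d[2:3], target)
  out <- array(0, dim = c(d[1], target[1], target[2]))
  for (s in seq_len(d[1])) out[s, , ] <- extract_window(x[s, , ], win)
  if (inherits(vol, c("image_volume", "mask_volume"))) {
    vol$data <- out
    attr(vol, "crop_window") <- win
    vol
  } else {
    attr(out, "crop_window") <- win
    out
  }
}

#' Re-embed a cropped prediction into the original volume geometry
#'
#' Inverse of [crop_to_shape()]: places each cropped slice back at the
#' window position, filling everything outside the window with 0.
#'
#' @param pred 3D array of cropped slices (or `mask_volume`).
#' @param win The `crop_window` attribute produced by [crop_to_shape()].
#' @return 3D array with the original `(slices, H, W)` shape.
#' @export
uncrop_volume <- function(pred, win) {
  x <- vol_data(pred)
  d <- win$img_dims
  n <- dim(x)[1]
  out <- array(0, dim = c(n, d[1], d[2]))
  r0 <- max(win$rows[1], 0L); r1 <- min(win$rows[2], d[1])
  c0 <- max(win$cols[1], 0L); c1 <- min(win$cols[2], d[2])
  if (r1 > r0 && c1 > c0)
    for (s in seq_len(n))
      out[s, (r0 + 1):r1, (c0 + 1):c1] <-
        x[s, (r0 - win$rows[1] + 1):(r1 - win$rows[1]),
          (c0 - win$cols[1] + 1):(c1 - win$cols[1])]
  out
}

#' Case-disjoint k-fold split
#'
#' Seeded shuffle followed by round-robin assignment, so folds are disjoint
#' and sizes differ by at most one (82 cases at k = 4 gives 21/21/20/20).
#'
#' @param case_ids Character or integer vector of case identifiers.
#' @param k Number of folds (default 4).
#' @param seed Integer seed for the shuffle.
#' @return A tibble with columns `case_id` and `fold`, plus attribute
#'   `"seed"`.
#' @export
make_folds <- function(case_ids, k = 4L, seed = 1L) {
  if (length(case_ids) < k) stop("fewer cases than folds")
  if (anyDuplicated(case_ids)) stop("case ids must be unique")
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(seed)
  shuffled <- sample(case_ids)
  fold <- rep_len(seq_len(k), length(case_ids))
  out <- tibble::tibble(case_id = shuffled, fold = fold)
  out <- out[order(match(out$case_id, case_ids)), ]
  attr(out, "seed") <- seed
  out
}

# ---- file formats ----------------------------------------------------------

#' Read / write volumes as NIfTI
#'
#' Volumes are stored with the slice axis last on disk (the conventional
#' NIfTI z axis) and presented in memory as `(slices, H, W)`. Spacing is
#' carried through the NIfTI pixdim; if missing, 1 mm is assumed with a
#' warning. Binary masks round-trip exactly.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol An `image_volume` or `mask_volume`.
#' @param id Case label for the returned object (default: file stem).
#' @return `read_volume`/`read_mask` return an `image_volume`/`mask_volume`;
#'   writers return `path` invisibly.
#' @export
read_volume <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  img <- RNifti::readNifti(path)
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(3, 1, 2))
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    warning("voxel spacing missing; defaulting to 1 mm")
    pd <- c(1, 1, 1)
  }
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  image_volume(arr, spacing = c(pd[3], pd[1], pd[2]), id = id)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  arr <- aperm(vol$data, c(2, 3, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vol$spacing[2], vol$spacing[3], vol$spacing[1])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, id = NULL) {
  v <- read_volume(path, id = id)
  mask_volume(round(v$data), spacing = v$spacing, id = v$id)
}

#' @rdname read_volume
#' @export
write_mask <- function(vol, path) write_volume(vol, path)

#' Read / write a volume as a directory of PNG slices
#'
#' One grayscale PNG per slice, named `slice_0000.png`, `slice_0001.png`, ...
#' so lexicographic order is stack order. PNG stores values in `[0, 1]`;
#' intensities are scaled by the range recorded in a sidecar `range.txt`
#' (written automatically) so HU volumes round-trip to PNG quantization
#' accuracy, and binary masks exactly.
#'
#' @param dir Directory holding (or to hold) the slice PNGs.
#' @param vol An `image_volume` or `mask_volume`.
#' @param id Case label (default: directory name).
#' @return `read_png_stack` returns an `image_volume`; the writer returns
#'   `dir` invisibly.
#' @export
read_png_stack <- function(dir, id = NULL) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG slices in ", dir)
  slices <- lapply(files, png::readPNG)
  arr <- array(0, dim = c(length(slices), nrow(slices[[1]]), ncol(slices[[1]])))
  for (s in seq_along(slices)) arr[s, , ] <- slices[[s]]
  rng_file <- file.path(dir, "range.txt")
  if (file.exists(rng_file)) {
    rng <- as.numeric(readLines(rng_file))
    arr <- arr * (rng[2] - rng[1]) + rng[1]
  }
  if (is.null(id)) id <- basename(dir)
  image_volume(arr, id = id)
}

#' @rdname read_png_stack
#' @export
write_png_stack <- function(vol, dir) {
  x <- vol_data(vol)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- range(x)
  if (rng[2] > rng[1]) {
    scaled <- (x - rng[1]) / (rng[2] - rng[1])
  } else {
    scaled <- x * 0
  }
  writeLines(format(rng, digits = 17), file.path(dir, "range.txt"))
  for (s in seq_len(dim(x)[1]))
    png::writePNG(scaled[s, , ], file.path(dir, sprintf("slice_%04d.png", s - 1)))
  invisible(dir)
}

#' Read / write ROI coordinate files
#'
#' CSV dialect of the semiautomated workflow: columns `case_id`,
#' `slice_index`, `min_row`, `max_row`, `min_col`, `max_col` (0-based,
#' half-open). One row per annotated slice; [roi_for_case()] pools a case's
#' rows into the single per-volume box used for cropping.
#'
#' @param path CSV file path.
#' @param df Data frame in the dialect above.
#' @return `read_roi_csv` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
read_roi_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read ROI file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "slice_index", "min_row", "max_row", "min_col", "max_col")
  if (!all(need %in% names(df)))
    stop("ROI file must have columns: ", paste(need, collapse = ", "))
  tibble::as_tibble(df)
}

#' @rdname read_roi_csv
#' @export
write_roi_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_roi_csv
#' @param roi_df Tibble from [read_roi_csv()].
#' @param case_id Case to pool.
#' @param margin Margin in pixels added around the pooled extremes.
#' @param img_dims Slice dims `(H, W)` for clamping.
#' @export
roi_for_case <- function(roi_df, case_id, img_dims, margin = 16L) {
  rows <- roi_df[roi_df$case_id == case_id, ]
  if (nrow(rows) == 0) stop("no ROI rows for case ", case_id)
  roi_box(min_row = max(0L, min(rows$min_row) - margin),
          max_row = min(img_dims[1], max(rows$max_row) + margin),
          min_col = max(0L, min(rows$min_col) - margin),
          max_col = min(img_dims[2], max(rows$max_col) + margin))
}

#' Per-slice ROI table from a mask volume
#'
#' Training-mode annotation: for every slice with at least one positive
#' voxel, the tight coordinate extremes (0-based, half-open) are recorded in
#' the ROI CSV dialect.
#'
#' @param mask A `mask_volume`.
#' @return Tibble in the [read_roi_csv()] dialect.
#' @export
roi_table_from_mask <- function(mask) {
  m <- vol_data(mask)
  id <- if (inherits(mask, "mask_volume")) mask$id else "case"
  rows <- list()
  for (s in seq_len(dim(m)[1])) {
    pos <- which(m[s, , ] > 0, arr.ind = TRUE)
    if (nrow(pos) == 0) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      case_id = id, slice_index = s - 1L,
      min_row = min(pos[, 1]) - 1L, max_row = max(pos[, 1]),
      min_col = min(pos[, 2]) - 1L, max_col = max(pos[, 2]))
  }
  if (length(rows) == 0) stop("no pancreas annotation: mask has no positive voxel")
  do.call(rbind, rows)
}
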