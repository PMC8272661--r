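test_that("HU windowing clips and maps linearly to [0,1]", {
  v <- image_volume(array(c(-500, -100, 70, 240, 500, 0), c(1, 2, 3)), id = "t")
  out <- truncate_and_normalize(v)
  expect_equal(out$data[1, 1, 1], 0)
  expect_equal(out$data[1, 2, 1], 0)
  expect_equal(out$data[1, 1, 2], 0.5)
  expect_equal(out$data[1, 2, 2], 1)
  expect_equal(out$data[1, 1, 3], 1)
  expect_equal(out$data[1, 2, 3], 100 / 340)
  expect_true(all(out$data >= 0 & out$data <= 1))
  expect_error(truncate_and_normalize(v, 10, 10), "below")
  expect_warning(truncate_and_normalize(array(1000, c(1, 2, 2))), "constant")
})

test_that("windowing is idempotent once normalized", {
  set.seed(10)
  v <- array(runif(60, -300, 400), c(3, 4, 5))
  once <- truncate_and_normalize(v)
  twice <- truncate_and_normalize(once, 0, 1)
  expect_equal(once, twice)
})

test_that("ROI extraction expands coordinate extremes with margin and clamping", {
  m <- array(0, c(2, 50, 120))
  m[1, 11, 21] <- 1                           # 0-based (10, 20)
  box <- roi_from_annotations(m, margin = 0)
  expect_equal(unclass(box)[c("min_row", "max_row", "min_col", "max_col")],
               list(min_row = 10L, max_row = 11L, min_col = 20L, max_col = 21L))
  # positives spanning 0-based rows [5, 30), cols [40, 90), margin 10
  m2 <- array(0, c(1, 50, 120))
  m2[1, 6:30, 41:90] <- 1
  box2 <- roi_from_annotations(m2, margin = 10)
  expect_equal(box2$min_row, 0L)              # 5 - 10 clamped
  expect_equal(box2$max_row, 40L)
  expect_equal(box2$min_col, 30L)
  expect_equal(box2$max_col, 100L)
  # huge margin saturates at the full image
  box3 <- roi_from_annotations(m2, margin = 1000)
  expect_equal(c(box3$min_row, box3$max_row, box3$min_col, box3$max_col),
               c(0L, 50L, 0L, 120L))
  expect_error(roi_from_annotations(array(0, c(1, 4, 4))), "no pancreas annotation")
})

test_that("cropping centers on the ROI, shifts inward at borders, pads small images", {
  # 512x512 slice, box centered at (256, 256) -> rows [160,352), cols [128,384)
  img <- array(rnorm(512 * 512), c(1, 512, 512))
  box <- roi_box(250, 262, 250, 262)
  out <- crop_to_shape(img, box, target = c(192, 256))
  win <- attr(out, "crop_window")
  expect_equal(win$rows, c(160, 352))
  expect_equal(win$cols, c(128, 384))
  expect_equal(dim(out), c(1, 192, 256))
  expect_equal(out[1, , ], img[1, 161:352, 129:384])
  # border box shifts inward instead of leaving the image
  boxb <- roi_box(0, 10, 0, 10)
  winb <- attr(crop_to_shape(img, boxb, target = c(192, 256)), "crop_window")
  expect_equal(winb$rows[1], 0)
  expect_equal(winb$cols[1], 0)
  # image smaller than target is zero-padded symmetrically
  small <- array(1, c(2, 100, 100))
  outs <- crop_to_shape(small, roi_box(40, 60, 40, 60), target = c(192, 256))
  expect_equal(dim(outs), c(2, 192, 256))
  expect_equal(sum(outs), 2 * 100 * 100)
  # mask positives survive the crop when the ROI fits the window
  mask <- array(0, c(2, 512, 512)); mask[, 250:260, 250:260] <- 1
  cm <- crop_to_shape(mask, box, target = c(192, 256))
  expect_equal(sum(cm), sum(mask))
})

test_that("uncropping inverts cropping on the window region", {
  set.seed(12)
  img <- array(rnorm(3 * 64 * 64), c(3, 64, 64))
  box <- roi_box(20, 40, 10, 30)
  crop <- crop_to_shape(img, box, target = c(32, 32))
  win <- attr(crop, "crop_window")
  back <- uncrop_volume(crop, win)
  expect_equal(dim(back), dim(img))
  expect_equal(back[, (win$rows[1] + 1):win$rows[2], (win$cols[1] + 1):win$cols[2]],
               img[, (win$rows[1] + 1):win$rows[2], (win$cols[1] + 1):win$cols[2]])
})

test_that("k-fold splits are seeded, disjoint and balanced (82 cases -> 21/21/20/20)", {
  ids <- sprintf("case%02d", 1:8)
  f <- make_folds(ids, k = 4, seed = 3)
  expect_equal(as.integer(table(f$fold)), rep(2L, 4))
  expect_setequal(f$case_id, ids)
  f2 <- make_folds(ids, k = 4, seed = 3)
  expect_identical(f, f2)
  f3 <- make_folds(ids, k = 4, seed = 4)
  expect_false(identical(f$fold, f3$fold))
  big <- make_folds(sprintf("c%03d", 1:82), k = 4, seed = 1)
  expect_equal(as.integer(sort(table(big$fold))), c(20L, 20L, 21L, 21L))
  expect_equal(anyDuplicated(big$case_id), 0L)
  expect_error(make_folds(letters[1:3], k = 4), "fewer")
})

test_that("NIfTI round-trip preserves masks exactly and anisotropic spacing", {
  set.seed(13)
  m <- mask_volume(rand_mask(c(5, 8, 9), 0.3), spacing = c(2.5, 0.7, 0.9), id = "rt")
  path <- tempfile(fileext = ".nii.gz")
  write_mask(m, path)
  back <- read_mask(path)
  expect_equal(back$data, m$data)
  expect_equal(back$spacing, m$spacing, tolerance = 1e-6)
  v <- image_volume(array(rnorm(5 * 8 * 9, 40, 30), c(5, 8, 9)), id = "img")
  p2 <- tempfile(fileext = ".nii.gz")
  write_volume(v, p2)
  expect_equal(read_volume(p2)$data, v$data, tolerance = 1e-6)
  expect_error(read_volume(tempfile()), "cannot read")
})

test_that("PNG slice stacks keep order and round-trip binary masks exactly", {
  set.seed(14)
  m <- rand_mask(c(12, 6, 7), 0.4)
  d <- tempfile()
  write_png_stack(mask_volume(m, id = "png"), d)
  files <- list.files(d, pattern = "png$")
  expect_equal(files, sprintf("slice_%04d.png", 0:11))  # lexicographic = stack order
  back <- read_png_stack(d)
  expect_equal(round(back$data), m)
  # an HU-range image survives to 8-bit quantization accuracy
  v <- array(runif(4 * 5 * 5, -100, 240), c(4, 5, 5))
  d2 <- tempfile()
  write_png_stack(image_volume(v, id = "hu"), d2)
  expect_equal(read_png_stack(d2)$data, v, tolerance = 340 / 255)
})

test_that("ROI CSV dialect round-trips and pools per-case boxes", {
  m <- array(0, c(3, 40, 40))
  m[1, 11:14, 6:9] <- 1
  m[3, 16:18, 21:24] <- 1
  tab <- roi_table_from_mask(mask_volume(m, id = "k"))
  expect_equal(nrow(tab), 2)                      # only annotated slices
  expect_equal(tab$slice_index, c(0L, 2L))
  expect_equal(tab$min_row[1], 10L)
  expect_equal(tab$max_row[1], 14L)
  path <- tempfile(fileext = ".csv")
  write_roi_csv(tab, path)
  back <- read_roi_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  box <- roi_for_case(back, "k", img_dims = c(40, 40), margin = 2)
  expect_equal(box$min_row, 8L)                   # pooled extremes +/- margin
  expect_equal(box$max_row, 20L)
  expect_equal(box$min_col, 3L)
  expect_equal(box$max_col, 26L)
  expect_error(roi_for_case(back, "missing", c(40, 40)), "no ROI rows")
  # the pooled box agrees with direct mask extremes
  direct <- roi_from_annotations(m, margin = 2)
  expect_equal(unclass(box), unclass(direct))
})

test_that("preprocessing keeps image and mask congruent and slice count fixed", {
  set.seed(15)
  img <- image_volume(array(rnorm(6 * 48 * 48, 60, 50), c(6, 48, 48)), id = "c")
  mask <- mask_volume(rand_mask(c(6, 48, 48), 0.02), id = "c")
  cfg <- run_config(model = dunet_spec(levels = 2, base_channels = 4),
                    crop = c(32, 32))
  samples <- prepare_slices(img, mask, cfg)
  expect_length(samples, 6)
  for (s in samples) {
    expect_equal(dim(s$x), c(32, 32))
    expect_equal(dim(s$y), c(32, 32))
    expect_true(all(s$x >= 0 & s$x <= 1))
    expect_true(all(s$y %in% c(0, 1)))
  }
})
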