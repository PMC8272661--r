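#' @useDynLib dunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# Internal: coerce a (C, H, W) map to the 4-d (C, H, W, 1) layout the compiled
# kernels use, remembering whether to drop the batch axis on the way out.
as_chw4 <- function(x, what = "feature map") {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop(what, " must be a 3-d (channels, height, width) or 4-d array", call. = FALSE)
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

drop_batch <- function(y, had3) {
  if (had3) { d <- dim(y); dim(y) <- d[1:3] }
  y
}

#' Regular sampling grid of a square convolution kernel
#'
#' The set of integer displacements, relative to the kernel center, that a
#' standard `k x k` convolution samples (dilation 1). For `k = 3` this is the
#' nine pairs \{-1, 0, 1\} x \{-1, 0, 1\}; deformable convolution perturbs
#' exactly these positions with learned offsets.
#'
#' @param k Odd kernel side length (default 3).
#' @return An integer matrix with `k^2` rows and columns `row`, `col`, in
#'   row-major kernel-point order (the order offset channels refer to).
#' @export
#' @examples
#' sampling_grid(3)
sampling_grid <- function(k = 3L) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("kernel side length must be a positive odd integer")
  pad <- k %/% 2L
  g <- expand.grid(col = seq_len(k) - 1L - pad, row = seq_len(k) - 1L - pad)
  m <- cbind(row = g$row, col = g$col)
  m[order(m[, "row"], m[, "col"]), , drop = FALSE]
}

#' Standard 2D convolution (cross-correlation), pad k/2, stride 1
#'
#' Computes `Y(p0) = sum_{p_n in G} W(p_n) * X(p0 + p_n)` over the regular
#' sampling grid, with zero padding outside the image, so output spatial
#' dimensions equal input dimensions.
#'
#' @param x Feature map, array `(channels, H, W)` (a batch axis
#'   `(channels, H, W, N)` is also accepted).
#' @param w Kernel weights, array `(k, k, in_channels, out_channels)` with odd
#'   `k`; row index is the vertical tap.
#' @param bias Optional per-output-channel bias (default zeros).
#' @return Feature map `(out_channels, H, W)` (batch axis preserved if given).
#' @export
standard_conv2d <- function(x, w, bias = NULL) {
  had3 <- length(dim(x)) == 3L
  x <- as_chw4(x)
  dw <- dim(w)
  if (is.null(dw) || length(dw) != 4L || dw[1] != dw[2])
    stop("kernel must be a (k, k, in_channels, out_channels) array with square spatial taps")
  if (dw[1] %% 2L == 0L) stop("kernel side length must be odd")
  if (dw[3] != dim(x)[1])
    stop("input has ", dim(x)[1], " channels but kernel expects ", dw[3])
  if (is.null(bias)) bias <- numeric(dw[4])
  if (length(bias) != dw[4]) stop("bias length must equal out_channels")
  drop_batch(cpp_conv2d_fwd(x, w, bias), had3)
}

#' Bilinear interpolation of a feature map at a fractional position
#'
#' Interpolates among the four lattice neighbors of `(q_row, q_col)` in
#' 0-based pixel coordinates (pixel centers at integers). Positions outside
#' the image contribute 0, giving a linear taper to zero across the one-pixel
#' border band — the same semantics as zero-padded convolution. Exact lattice
#' points return the stored value exactly.
#'
#' @param x Feature map `(channels, H, W)`.
#' @param q_row,q_col Finite real query coordinates.
#' @param channel 1-based channel index.
#' @return A single interpolated value.
#' @export
bilinear_sample <- function(x, q_row, q_col, channel = 1L) {
  if (!is.finite(q_row) || !is.finite(q_col))
    stop("query coordinates must be finite")
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("x must be a (channels, H, W) array")
  H <- d[2]; W <- d[3]
  if (q_row <= -1 || q_row >= H || q_col <= -1 || q_col >= W) return(0)
  r0 <- floor(q_row); c0 <- floor(q_col)
  fr <- q_row - r0; fc <- q_col - c0
  px <- function(r, cc) {
    if (r < 0 || r >= H || cc < 0 || cc >= W) return(0)
    x[channel, r + 1, cc + 1]
  }
  (1 - fr) * ((1 - fc) * px(r0, c0) + fc * px(r0, c0 + 1)) +
    fr * ((1 - fc) * px(r0 + 1, c0) + fc * px(r0 + 1, c0 + 1))
}

#' Deformable 2D convolution with learned sampling offsets
#'
#' Each kernel sampling position is displaced by a per-output-location,
#' per-kernel-point 2D offset before the weighted sum:
#' `Y(p0) = sum_n W(p_n) * X(p0 + p_n + dp_n(p0))`, where the displaced
#' positions are read with bilinear interpolation so fractional offsets are
#' allowed and gradients flow to the offsets. With a zero offset field the
#' result equals [standard_conv2d()].
#'
#' @inheritParams standard_conv2d
#' @param offsets Offset field, array `(2*k^2, H, W)` (or with batch axis):
#'   channel `2m-1` is the vertical (row) displacement and channel `2m` the
#'   horizontal (column) displacement of kernel point `m`, kernel points in
#'   row-major order. Units are pixels; fractional values allowed, no
#'   magnitude cap.
#' @return Feature map `(out_channels, H, W)`.
#' @export
deformable_conv2d <- function(x, w, offsets, bias = NULL) {
  had3 <- length(dim(x)) == 3L
  x <- as_chw4(x)
  offsets <- as_chw4(offsets, what = "offset field")
  dw <- dim(w)
  if (is.null(dw) || length(dw) != 4L || dw[1] != dw[2])
    stop("kernel must be a (k, k, in_channels, out_channels) array")
  k <- dw[1]
  if (dim(offsets)[1] != 2L * k * k)
    stop("offset field must have 2*k^2 = ", 2 * k * k,
         " channels, got ", dim(offsets)[1])
  if (!all(dim(offsets)[2:4] == dim(x)[2:4]))
    stop("offset field spatial dims must match the feature map")
  if (dw[3] != dim(x)[1])
    stop("input has ", dim(x)[1], " channels but kernel expects ", dw[3])
  if (is.null(bias)) bias <- numeric(dw[4])
  drop_batch(cpp_deform_fwd(x, w, bias, offsets), had3)
}

#' Convolutional offset layer
#'
#' A standard convolution whose output is the offset field of a deformable
#' convolution: `2*k^2` output channels, one (vertical, horizontal) pair per
#' kernel point, predicted per pixel from the preceding feature map. With
#' zero weights and bias the produced field is identically zero, so a
#' deformable block initialized this way behaves exactly like a standard one.
#'
#' @inheritParams standard_conv2d
#' @param k Kernel side length of the deformable convolution the offsets feed
#'   (default 3); `w` must have `2*k^2` output channels.
#' @return Offset field `(2*k^2, H, W)`.
#' @export
conv_offset_layer <- function(x, w, bias = NULL, k = 3L) {
  dw <- dim(w)
  if (is.null(dw) || length(dw) != 4L || dw[4] != 2L * k * k)
    stop("offset-layer kernel must have 2*k^2 = ", 2 * k * k, " output channels")
  standard_conv2d(x, w, bias)
}

#' Brute-force reference deformable convolution
#'
#' Independent nested-loop evaluation of the deformable convolution sum, used
#' as the oracle in tests and verification: for every output pixel, kernel
#' point and channel it forms the displaced sampling position explicitly and
#' interpolates with [bilinear_sample()]. Same additive cross-correlation
#' convention, zero-padding semantics and offset-channel ordering as
#' [deformable_conv2d()], but sharing no code with the compiled path.
#'
#' @inheritParams deformable_conv2d
#' @return Feature map `(out_channels, H, W)`.
#' @export
deformable_conv2d_reference <- function(x, w, offsets, bias = NULL) {
  d <- dim(x); dw <- dim(w)
  C <- d[1]; H <- d[2]; W <- d[3]
  k <- dw[1]; pad <- k %/% 2; Cout <- dw[4]
  if (is.null(bias)) bias <- numeric(Cout)
  y <- array(0, dim = c(Cout, H, W))
  grid <- sampling_grid(k)
  for (co in seq_len(Cout)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        acc <- bias[co]
        for (m in seq_len(k * k)) {
          dr <- grid[m, "row"]; dc <- grid[m, "col"]
          qr <- (i - 1) + dr + offsets[2 * m - 1, i, j]
          qc <- (j - 1) + dc + offsets[2 * m, i, j]
          for (ci in seq_len(C)) {
            acc <- acc + w[dr + pad + 1, dc + pad + 1, ci, co] *
              bilinear_sample(x, qr, qc, ci)
          }
        }
        y[co, i, j] <- acc
      }
    }
  }
  y
}
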