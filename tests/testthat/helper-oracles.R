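# Independent brute-force oracles and small fixture builders used across the
# test files. These share no code with the compiled kernels they check.

# Nested-loop standard convolution (cross-correlation, zero padding), written
# directly from the definition.
oracle_conv2d <- function(x, w, bias = NULL) {
  d <- dim(x); dw <- dim(w)
  C <- d[1]; H <- d[2]; W <- d[3]
  k <- dw[1]; pad <- k %/% 2; Cout <- dw[4]
  if (is.null(bias)) bias <- numeric(Cout)
  y <- array(0, dim = c(Cout, H, W))
  for (co in seq_len(Cout))
    for (i in seq_len(H))
      for (j in seq_len(W)) {
        acc <- bias[co]
        for (ci in seq_len(C))
          for (a in seq_len(k))
            for (b in seq_len(k)) {
              ii <- i + a - 1 - pad
              jj <- j + b - 1 - pad
              if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
                acc <- acc + w[a, b, ci, co] * x[ci, ii, jj]
            }
        y[co, i, j] <- acc
      }
  y
}

# Scalar bilinear interpolation from the four-corner formula, zero outside.
oracle_bilinear <- function(x, qr, qc, ch = 1) {
  H <- dim(x)[2]; W <- dim(x)[3]
  r0 <- floor(qr); c0 <- floor(qc)
  fr <- qr - r0; fc <- qc - c0
  val <- 0
  for (dr in 0:1) for (dc in 0:1) {
    r <- r0 + dr; cc <- c0 + dc
    wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
    if (r >= 0 && r < H && cc >= 0 && cc < W)
      val <- val + wgt * x[ch, r + 1, cc + 1]
  }
  val
}

# Scalar recomputation of the focal generalized Dice loss straight from its
# definition, with linear class weighting.
oracle_fgdl <- function(p, g, eps, gamma) {
  total <- 0
  for (l in 1:2) {
    pl <- if (l == 1) p else 1 - p
    gl <- if (l == 1) g else 1 - g
    wl <- if (sum(gl) == 0) 1e5 else 1 / sum(gl)
    bracket <- 1 - (2 * wl * sum(pl * gl) + eps) / (wl * sum(pl + gl) + eps)
    bracket <- min(max(bracket, 0), 1)
    total <- total + bracket^(1 / gamma)
  }
  total
}

rand_feature_map <- function(C, H, W, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(C * H * W), dim = c(C, H, W))
}

rand_mask <- function(dims, p = 0.3) {
  array(stats::rbinom(prod(dims), 1, p), dim = dims)
}

# Small phantom-backed training set used by the training-loop tests.
tiny_phantom_samples <- function(n_volumes = 2, seed = 1, slices = 4) {
  cfg <- phantom_config(image_size = c(32, 32), slices_per_volume = slices,
                        target_area_fraction = 0.008, seed = seed)
  config <- run_config(model = dunet_spec(levels = 2L, base_channels = 4L,
                                          deformable_levels = 2L),
                       crop = c(32L, 32L), epochs = 1L, batch_size = 4L)
  samples <- list()
  for (i in seq_len(n_volumes)) {
    ph <- generate_phantom_volume(cfg, index = i)
    samples <- c(samples, prepare_slices(ph$image, ph$mask, config))
  }
  list(samples = samples, config = config, cfg = cfg)
}
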