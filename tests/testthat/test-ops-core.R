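test_that("sampling grid of a 3x3 kernel is the nine symmetric displacements", {
  g <- sampling_grid(3)
  expect_equal(nrow(g), 9L)
  expect_setequal(paste(g[, "row"], g[, "col"]),
                  paste(rep(-1:1, each = 3), rep(-1:1, 3)))
  expect_true(any(g[, "row"] == 0 & g[, "col"] == 0))
  # symmetric about the center
  expect_setequal(paste(g[, "row"], g[, "col"]), paste(-g[, "row"], -g[, "col"]))
  expect_error(sampling_grid(4), "odd")
})

test_that("standard convolution matches the brute-force oracle and its identities", {
  # zero input
  w <- array(rnorm(9), dim = c(3, 3, 1, 1))
  z <- standard_conv2d(array(0, c(1, 5, 5)), w)
  expect_equal(z, array(0, c(1, 5, 5)))
  # single impulse under an all-ones kernel: full map from the oracle
  x <- array(0, c(1, 3, 3)); x[1, 2, 2] <- 1
  ones <- array(1, c(3, 3, 1, 1))
  expect_equal(standard_conv2d(x, ones), oracle_conv2d(x, ones))
  expect_equal(standard_conv2d(x, ones)[1, 2, 2], 1)
  expect_true(all(standard_conv2d(x, ones) == 1))
  # delta kernel is the identity
  delta <- array(0, c(3, 3, 1, 1)); delta[2, 2, 1, 1] <- 1
  x2 <- rand_feature_map(1, 6, 7, seed = 5)
  expect_equal(standard_conv2d(x2, delta), x2)
  # random multi-channel instances against the oracle
  set.seed(11)
  for (rep in 1:5) {
    C <- sample(1:3, 1); Cout <- sample(1:3, 1)
    x3 <- rand_feature_map(C, sample(3:7, 1), sample(3:7, 1))
    w3 <- array(rnorm(9 * C * Cout), c(3, 3, C, Cout))
    b3 <- rnorm(Cout)
    expect_equal(standard_conv2d(x3, w3, b3), oracle_conv2d(x3, w3, b3),
                 tolerance = 1e-12)
  }
  # channel mismatch is an explicit error
  expect_error(standard_conv2d(rand_feature_map(2, 4, 4), w), "channels")
})

test_that("bilinear sampling interpolates, is exact on the lattice, tapers to zero", {
  x <- array(0, c(1, 4, 5)); x[1, 3, 4] <- 7
  expect_identical(bilinear_sample(x, 2, 3), 7)
  x2 <- array(0, c(1, 2, 2)); x2[1, , ] <- matrix(c(0, 1, 2, 3), 2, byrow = TRUE)
  expect_equal(bilinear_sample(x2, 0.5, 0.5), 1.5)
  expect_equal(bilinear_sample(x2, 0.25, 0.75), 1.25)
  # against the scalar oracle at random positions, including outside
  set.seed(3)
  x3 <- rand_feature_map(2, 5, 6)
  for (i in 1:50) {
    qr <- runif(1, -2, 6); qc <- runif(1, -2, 7); ch <- sample(1:2, 1)
    expect_equal(bilinear_sample(x3, qr, qc, ch), oracle_bilinear(x3, qr, qc, ch))
  }
  expect_equal(bilinear_sample(x3, -1, 2), 0)
  expect_equal(bilinear_sample(x3, 5, 2), 0)
  # partition of unity in the interior: constant image stays constant
  ones <- array(1, c(1, 5, 5))
  for (i in 1:20) {
    qr <- runif(1, 0, 4); qc <- runif(1, 0, 4)
    expect_equal(bilinear_sample(ones, qr, qc), 1)
  }
  expect_error(bilinear_sample(x3, NaN, 1), "finite")
})

test_that("deformable convolution reduces to standard at zero offset over many instances", {
  set.seed(21)
  for (rep in 1:100) {
    C <- sample(1:2, 1); Cout <- sample(1:2, 1)
    H <- sample(3:8, 1); W <- sample(3:8, 1)
    x <- rand_feature_map(C, H, W)
    w <- array(rnorm(9 * C * Cout), c(3, 3, C, Cout))
    off <- array(0, c(18, H, W))
    expect_equal(deformable_conv2d(x, w, off), standard_conv2d(x, w),
                 tolerance = 1e-6)
  }
})

test_that("deformable convolution matches the nested-loop oracle on random fractional offsets", {
  set.seed(31)
  for (rep in 1:20) {
    C <- sample(1:2, 1); Cout <- sample(1:2, 1)
    H <- sample(4:8, 1); W <- sample(4:8, 1)
    x <- rand_feature_map(C, H, W)
    w <- array(rnorm(9 * C * Cout), c(3, 3, C, Cout))
    b <- rnorm(Cout)
    off <- array(rnorm(18 * H * W, sd = 1.2), c(18, H, W))
    expect_equal(deformable_conv2d(x, w, off, b),
                 deformable_conv2d_reference(x, w, off, b), tolerance = 1e-5)
  }
})

test_that("integer offsets gather from the shifted image on interior pixels", {
  set.seed(41)
  x <- rand_feature_map(1, 8, 8)
  w <- array(rnorm(9), c(3, 3, 1, 1))
  dr <- 1; dc <- 2
  off <- array(0, c(18, 8, 8))
  off[seq(1, 17, by = 2), , ] <- dr
  off[seq(2, 18, by = 2), , ] <- dc
  shifted <- array(0, c(1, 8, 8))
  shifted[1, 1:(8 - dr), 1:(8 - dc)] <- x[1, (1 + dr):8, (1 + dc):8]
  got <- deformable_conv2d(x, w, off)
  want <- standard_conv2d(shifted, w)
  interior_r <- 2:(8 - dr - 1); interior_c <- 2:(8 - dc - 1)
  expect_equal(got[1, interior_r, interior_c], want[1, interior_r, interior_c],
               tolerance = 1e-12)
})

test_that("deformable convolution is linear in the input for a fixed offset field", {
  set.seed(51)
  x1 <- rand_feature_map(2, 6, 6); x2 <- rand_feature_map(2, 6, 6)
  w <- array(rnorm(9 * 2 * 2), c(3, 3, 2, 2))
  off <- array(rnorm(18 * 36, sd = 0.8), c(18, 6, 6))
  a <- 1.7; b <- -0.4
  lhs <- deformable_conv2d(a * x1 + b * x2, w, off)
  rhs <- a * deformable_conv2d(x1, w, off) + b * deformable_conv2d(x2, w, off)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("offset gradients match central differences at non-lattice offsets", {
  set.seed(61)
  for (rep in 1:20) {
    C <- sample(1:2, 1); Cout <- sample(1:2, 1)
    x <- array(rnorm(C * 16), c(C, 4, 4, 1))
    w <- array(rnorm(9 * C * Cout), c(3, 3, C, Cout))
    b <- rnorm(Cout)
    off <- array(runif(18 * 16, -0.9, 0.9) + 0.07, c(18, 4, 4, 1))
    wt <- array(rnorm(Cout * 16), c(Cout, 4, 4, 1))
    ana <- dunet:::cpp_deform_bwd(x, w, off, wt)$doff
    # probe 6 random offset entries with central differences
    idx <- sample(length(off), 6)
    h <- 1e-6
    for (i in idx) {
      o1 <- off; o1[i] <- o1[i] + h
      o2 <- off; o2[i] <- o2[i] - h
      num <- (sum(wt * dunet:::cpp_deform_fwd(x, w, b, o1)) -
              sum(wt * dunet:::cpp_deform_fwd(x, w, b, o2))) / (2 * h)
      denom <- max(1e-6, abs(num), abs(ana[i]))
      expect_lt(abs(num - ana[i]) / denom, 1e-3)
    }
  }
})

test_that("offset layer is a standard convolution with 2k^2 channels and zero init gives zero field", {
  set.seed(71)
  x <- rand_feature_map(3, 5, 5)
  w0 <- array(0, c(3, 3, 3, 18))
  expect_equal(conv_offset_layer(x, w0), array(0, c(18, 5, 5)))
  # delta kernel on one offset channel copies the input channel
  wd <- array(0, c(3, 3, 3, 18)); wd[2, 2, 2, 5] <- 1
  expect_equal(conv_offset_layer(x, wd)[5, , ], x[2, , ])
  # random weights equal the standard-conv oracle
  wr <- array(rnorm(3 * 3 * 3 * 18), c(3, 3, 3, 18))
  expect_equal(conv_offset_layer(x, wr), oracle_conv2d(x, wr), tolerance = 1e-12)
  expect_error(conv_offset_layer(x, array(0, c(3, 3, 3, 12))), "2\\*k\\^2")
})

test_that("deformable convolution rejects malformed offset fields", {
  x <- rand_feature_map(1, 4, 4, seed = 1)
  w <- array(rnorm(9), c(3, 3, 1, 1))
  expect_error(deformable_conv2d(x, w, array(0, c(12, 4, 4))), "channels")
  expect_error(deformable_conv2d(x, w, array(0, c(18, 3, 4))), "spatial")
})

test_that("non-integer offsets at exact lattice points do not produce NaN", {
  x <- rand_feature_map(1, 5, 5, seed = 2)
  w <- array(rnorm(9), c(3, 3, 1, 1))
  off <- array(0, c(18, 5, 5))
  off[1, , ] <- 1.0  # displaced but exactly on the lattice
  y <- deformable_conv2d(x, w, off)
  expect_true(all(is.finite(y)))
})
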