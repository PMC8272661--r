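# Internal layer primitives with explicit forward/backward passes.
# All activations are arrays (C, H, W, N). Parameters live in plain lists so
# the optimizer can walk them generically.

he_init <- function(k, cin, cout, gain = 1, zero_mean = FALSE) {
  sd <- gain * sqrt(2 / (k * k * cin))
  w <- array(stats::rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout))
  if (zero_mean && k > 1) {
    # project each 2D tap onto the zero-sum subspace: filters start DC-free
    # (pure local-contrast detectors); the mean component stays learnable
    mu <- apply(w, c(3, 4), mean)
    w <- w - aperm(array(mu, dim = c(cin, cout, k, k)), c(3, 4, 1, 2))
  }
  w
}

new_conv <- function(cin, cout, k = 3L, init = c("he", "zero"), gain = 1,
                     zero_mean = FALSE, bias0 = 0) {
  init <- match.arg(init)
  w <- if (init == "zero") array(0, dim = c(k, k, cin, cout))
       else he_init(k, cin, cout, gain, zero_mean)
  list(type = "conv", w = w, b = rep(bias0, cout))
}

new_tconv <- function(cin, cout) {
  sd <- sqrt(2 / (4 * cin))
  list(type = "tconv",
       w = array(stats::rnorm(4 * cin * cout, sd = sd), dim = c(2, 2, cin, cout)),
       b = numeric(cout))
}

# Batch-norm scale initialization. A gain above 1 raises the operating scale
# of the features each block emits; with the zero-initialized sigmoid head
# this sets the ratio between feature magnitude and the head's per-step
# parameter movement, i.e. the head's effective step size. Interior blocks
# are unaffected (the next batch norm renormalizes whatever scale arrives).
bn_gamma_init <- 15

new_bn <- function(ch, momentum = 0.1, eps = 1e-5, gamma0 = bn_gamma_init) {
  list(type = "bn", gamma = rep(gamma0, ch), beta = numeric(ch),
       run_mean = numeric(ch), run_var = rep(1, ch),
       momentum = momentum, eps = eps)
}

conv_fwd <- function(layer, x) {
  y <- cpp_conv2d_fwd(x, layer$w, layer$b)
  list(y = y, cache = list(x = x))
}

conv_bwd <- function(layer, cache, dy) {
  g <- cpp_conv2d_bwd(cache$x, layer$w, dy)
  list(dx = g$dx, grads = list(w = g$dw, b = g$db))
}

tconv_fwd <- function(layer, x) {
  list(y = cpp_tconv2_fwd(x, layer$w, layer$b), cache = list(x = x))
}

tconv_bwd <- function(layer, cache, dy) {
  g <- cpp_tconv2_bwd(cache$x, layer$w, dy)
  list(dx = g$dx, grads = list(w = g$dw, b = g$db))
}

# Batch norm over (H, W, N) per channel. Training mode uses batch statistics
# (biased variance, as is conventional) and updates running statistics in the
# returned layer; eval mode uses the stored running statistics.
bn_fwd <- function(layer, x, train) {
  if (train) {
    mu <- rowMeans(x, dims = 1)
    xc <- sweep(x, 1, mu)
    v <- rowMeans(xc * xc, dims = 1)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    xc <- sweep(x, 1, mu)
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xc, 1, istd, `*`)
  y <- sweep(sweep(xhat, 1, layer$gamma, `*`), 1, layer$beta, `+`)
  list(y = y, cache = list(xhat = xhat, istd = istd, train = train),
       layer = layer)
}

bn_bwd <- function(layer, cache, dy) {
  dgamma <- rowSums(dy * cache$xhat, dims = 1)
  dbeta <- rowSums(dy, dims = 1)
  if (cache$train) {
    m <- prod(dim(dy)[-1])
    # dx = gamma*istd * (dy - dbeta/m - xhat * dgamma/m)
    dx <- sweep(dy, 1, dbeta / m) - sweep(cache$xhat, 1, dgamma / m, `*`)
    dx <- sweep(dx, 1, layer$gamma * cache$istd, `*`)
  } else {
    dx <- sweep(dy, 1, layer$gamma * cache$istd, `*`)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, cache = m)
}

relu_bwd <- function(cache, dy) dy * cache

pool_fwd <- function(x) {
  r <- cpp_maxpool2_fwd(x)
  list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
}

pool_bwd <- function(cache, dy) cpp_maxpool2_bwd(dy, cache$idx, as.integer(cache$xdim))

# Nearest-neighbor 2x upsampling (for upsample_mode = "interp_conv").
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  H <- d[2] / 2; W <- d[3] / 2
  o <- dy[, seq(1, d[2], by = 2), seq(1, d[3], by = 2), , drop = FALSE]
  o + dy[, seq(2, d[2], by = 2), seq(1, d[3], by = 2), , drop = FALSE] +
    dy[, seq(1, d[2], by = 2), seq(2, d[3], by = 2), , drop = FALSE] +
    dy[, seq(2, d[2], by = 2), seq(2, d[3], by = 2), , drop = FALSE]
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- Adam ------------------------------------------------------------------

# state: list of m/v mirrors of the flat parameter list
adam_init <- function(params) {
  zeros <- lapply(params, function(p) {
    z <- p; z[] <- 0; z
  })
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}
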