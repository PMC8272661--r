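#' Loss configuration for Dice-family segmentation losses
#'
#' @param kind One of `"dice_two_sided"`, `"generalized_dice"`,
#'   `"focal_generalized_dice"`.
#' @param epsilon Small positive smoothing constant added to numerators and
#'   denominators for numerical stability. Default `1e-5`.
#' @param gamma Focal exponent of the focal generalized Dice loss; the
#'   per-class Dice complements are raised to `1/gamma`. Must lie in
#'   `[1, 3]`; default `4/3`.
#' @param weighting Class-weight definition for the generalized losses:
#'   `"linear"` (default) uses `w_l = 1 / sum(g_l)`; `"squared"` uses
#'   `w_l = 1 / sum(g_l)^2`.
#' @return A `loss_config` object.
#' @export
loss_config <- function(kind = c("focal_generalized_dice", "dice_two_sided",
                                 "generalized_dice"),
                        epsilon = 1e-5, gamma = 4 / 3,
                        weighting = c("linear", "squared")) {
  kind <- match.arg(kind)
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (!is.numeric(gamma) || gamma < 1 || gamma > 3)
    stop("gamma must lie in [1, 3]")
  structure(list(kind = kind, epsilon = epsilon, gamma = gamma,
                 weighting = match.arg(weighting)),
            class = "loss_config")
}

check_prob_pair <- function(p, g) {
  if (length(p) != length(g)) stop("p and g must have congruent shapes")
  if (any(p < 0 | p > 1)) stop("predicted probabilities must lie in [0, 1]")
  if (any(g != 0 & g != 1)) stop("ground truth must be binary {0, 1}")
}

# class weights from ground truth; empty-class guard: w = 1/eps_w
class_weights <- function(g, weighting, eps_w = 1e-5) {
  s1 <- sum(g); s2 <- length(g) - s1
  f <- function(s) {
    if (s == 0) return(1 / eps_w)
    if (weighting == "squared") 1 / s^2 else 1 / s
  }
  c(f(s1), f(s2))
}

#' Two-sided soft binary Dice loss
#'
#' `L = 1 - (sum(p*g) + eps) / (sum(p + g) + eps)
#'        - (sum((1-p)*(1-g)) + eps) / (sum(2 - p - g) + eps)`.
#' Each one-sided ratio saturates at about 1/2 for a perfect prediction, so
#' the loss approaches 0 when `p = g` and 1 under total mismatch.
#'
#' @param p Predicted per-voxel probabilities in `[0, 1]` (any shape).
#' @param g Binary ground truth, congruent with `p`.
#' @param cfg A [loss_config()]; only `epsilon` is used.
#' @return Scalar loss value.
#' @export
dice_loss <- function(p, g, cfg = loss_config("dice_two_sided")) {
  check_prob_pair(p, g)
  eps <- cfg$epsilon
  1 - (sum(p * g) + eps) / (sum(p + g) + eps) -
    (sum((1 - p) * (1 - g)) + eps) / (sum(2 - p - g) + eps)
}

dice_loss_grad <- function(p, g, eps) {
  A <- sum(p * g) + eps
  B <- sum(p + g) + eps
  C <- sum((1 - p) * (1 - g)) + eps
  D <- sum(2 - p - g) + eps
  val <- 1 - A / B - C / D
  grad <- -(g * B - A) / B^2 - (-(1 - g) * D + C) / D^2
  list(value = val, grad = grad)
}

# per-class sums for the 2-class construction: class 1 = (p, g),
# class 2 = elementwise complement (1-p, 1-g)
class_sums <- function(p, g) {
  S1 <- sum(p * g); T1 <- sum(p) + sum(g)
  n <- length(p)
  S2 <- n - T1 + S1                    # sum((1-p)(1-g))
  T2 <- 2 * n - T1                     # sum((1-p)+(1-g))
  list(S = c(S1, S2), T = c(T1, T2))
}

#' Generalized Dice loss
#'
#' Two-class generalized Dice loss with class weights inversely related to
#' class size:
#' `GDL = 1 - 2 * sum_l(w_l * sum_i(p_li * g_li)) / sum_l(w_l * sum_i(p_li + g_li))`,
#' where class 1 is the foreground `(p, g)` and class 2 its complement.
#' `w_l = 1/sum(g_l)` under the default `"linear"` weighting, `1/sum(g_l)^2`
#' under `"squared"`. An empty class gets weight `1/1e-5` so the loss is
#' always finite (the cross-class denominator is strictly positive for any
#' non-empty image, so no smoothing term is needed here).
#'
#' @inheritParams dice_loss
#' @param cfg A [loss_config()]; only `weighting` is used.
#' @return Scalar loss in `[0, 1]`.
#' @export
generalized_dice_loss <- function(p, g, cfg = loss_config("generalized_dice")) {
  check_prob_pair(p, g)
  w <- class_weights(g, cfg$weighting)
  cs <- class_sums(p, g)
  1 - 2 * sum(w * cs$S) / sum(w * cs$T)
}

generalized_dice_loss_grad <- function(p, g, eps, weighting) {
  w <- class_weights(g, weighting)
  cs <- class_sums(p, g)
  num <- sum(w * cs$S)
  den <- sum(w * cs$T)
  val <- 1 - 2 * num / den
  dnum <- w[1] * g - w[2] * (1 - g)
  dden <- w[1] - w[2]
  grad <- -2 * (dnum * den - num * dden) / den^2
  list(value = val, grad = grad)
}

#' Focal generalized Dice loss
#'
#' Per-class generalized-Dice complements raised to the power `1/gamma` and
#' summed over the two classes:
#' `FGDL = sum_l [1 - (2*w_l*sum_i(p_li*g_li) + eps) / (w_l*sum_i(p_li+g_li) + eps)]^(1/gamma)`.
#' With `gamma > 1` the fractional power amplifies the contribution of
#' poorly-overlapping ("hard") classes near convergence, focusing training on
#' them; `gamma = 1` recovers the plain sum of per-class complements. Each
#' bracket is clamped to `[0, 1]` before the power.
#'
#' @inheritParams dice_loss
#' @param cfg A [loss_config()]; `epsilon`, `gamma` and `weighting` are used.
#' @return Scalar loss in `[0, 2]`.
#' @export
focal_generalized_dice_loss <- function(p, g,
                                        cfg = loss_config("focal_generalized_dice")) {
  check_prob_pair(p, g)
  fgdl_brackets(p, g, cfg$epsilon, cfg$weighting, value_only = TRUE, gamma = cfg$gamma)
}

fgdl_brackets <- function(p, g, eps, weighting, gamma, value_only = FALSE) {
  w <- class_weights(g, weighting)
  cs <- class_sums(p, g)
  b <- 1 - (2 * w * cs$S + eps) / (w * cs$T + eps)
  b <- pmin(pmax(b, 0), 1)
  val <- sum(b^(1 / gamma))
  if (value_only) return(val)
  list(value = val, b = b, w = w, cs = cs)
}

focal_generalized_dice_loss_grad <- function(p, g, eps, weighting, gamma,
                                             bracket_floor = 1e-7) {
  r <- fgdl_brackets(p, g, eps, weighting, gamma)
  w <- r$w; cs <- r$cs
  # dR_l/dp, with R_l the per-class ratio; bracket b_l = 1 - R_l
  den <- w * cs$T + eps
  Rl <- (2 * w * cs$S + eps) / den
  dS1 <- g;         dT1 <- 1
  dS2 <- -(1 - g);  dT2 <- -1
  dR1 <- (2 * w[1] * dS1 - Rl[1] * w[1] * dT1) / den[1]
  dR2 <- (2 * w[2] * dS2 - Rl[2] * w[2] * dT2) / den[2]
  bg <- pmax(r$b, bracket_floor)      # guard the diverging power derivative
  coef <- (1 / gamma) * bg^(1 / gamma - 1)
  grad <- -coef[1] * dR1 - coef[2] * dR2
  list(value = r$value, grad = grad)
}

#' Evaluate a configured loss (value and gradient)
#'
#' Dispatches on `cfg$kind` and returns both the scalar loss and its
#' elementwise gradient with respect to the predicted probabilities — the
#' form consumed by the training loop.
#'
#' @inheritParams dice_loss
#' @param cfg A [loss_config()].
#' @return List with elements `value` (scalar) and `grad` (same shape as `p`).
#' @export
seg_loss <- function(p, g, cfg = loss_config()) {
  check_prob_pair(p, g)
  r <- switch(cfg$kind,
    dice_two_sided = dice_loss_grad(p, g, cfg$epsilon),
    generalized_dice = generalized_dice_loss_grad(p, g, cfg$epsilon, cfg$weighting),
    focal_generalized_dice =
      focal_generalized_dice_loss_grad(p, g, cfg$epsilon, cfg$weighting, cfg$gamma))
  if (!is.null(dim(p))) dim(r$grad) <- dim(p)
  r
}
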