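#' Training objective configuration
#'
#' The objective is an affine combination of binary cross-entropy (BCE)
#' and soft Dice loss: `lambda_bce * BCE + (1 - lambda_bce) * Dice`.
#' Equal weighting is the default; the weight, the Dice smoothing term and
#' the BCE probability clamp are all exposed and logged with training
#' history.
#'
#' @param lambda_bce BCE weight in `[0, 1]`; the Dice weight is
#'   `1 - lambda_bce`.
#' @param smooth_eps positive Dice smoothing constant (added to numerator
#'   and denominator).
#' @param prob_clip_eps BCE log-argument clamp; probabilities are clipped
#'   to `[prob_clip_eps, 1 - prob_clip_eps]`. Must lie in (0, 0.5).
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda_bce = 0.5, smooth_eps = 1.0,
                        prob_clip_eps = 1e-7) {
  if (lambda_bce < 0 || lambda_bce > 1)
    stop("lambda_bce must lie in [0, 1]")
  if (smooth_eps <= 0) stop("smooth_eps must be positive")
  if (prob_clip_eps <= 0 || prob_clip_eps >= 0.5)
    stop("prob_clip_eps must lie in (0, 0.5)")
  structure(list(lambda_bce = lambda_bce, smooth_eps = smooth_eps,
                 prob_clip_eps = prob_clip_eps), class = "loss_config")
}

loss_pair <- function(pred, target) {
  p <- grid_data_any(pred)
  y <- grid_data_any(target)
  if (!identical(dim(p), dim(y)))
    stop("prediction and target shapes differ")
  list(p = p, y = y)
}

grid_data_any <- function(x) {
  if (inherits(x, c("les_volume", "les_mask", "les_probmap"))) x$data
  else x
}

#' Binary cross-entropy loss
#'
#' Mean over voxels of `-(y log p + (1 - y) log(1 - p))` with `p` clamped
#' to `[prob_clip_eps, 1 - prob_clip_eps]`.
#'
#' @param pred probability grid (array or [les_probmap()]), values in
#'   `[0, 1]`.
#' @param target binary grid (array or [les_mask()]).
#' @param prob_clip_eps clamp width (see [loss_config()]).
#' @return Non-negative scalar.
#' @export
bce_loss <- function(pred, target, prob_clip_eps = 1e-7) {
  pt <- loss_pair(pred, target)
  pc <- pmin(pmax(pt$p, prob_clip_eps), 1 - prob_clip_eps)
  -mean(pt$y * log(pc) + (1 - pt$y) * log(1 - pc))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * y) + smooth_eps) / (sum(p) + sum(y) + smooth_eps)`,
#' summed over all voxels of the sample. Zero for a perfect prediction; the
#' smoothing term makes the empty-vs-empty case zero as well.
#'
#' @inheritParams bce_loss
#' @param smooth_eps positive smoothing constant.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, smooth_eps = 1.0) {
  pt <- loss_pair(pred, target)
  1 - (2 * sum(pt$p * pt$y) + smooth_eps) /
    (sum(pt$p) + sum(pt$y) + smooth_eps)
}

#' Combined BCE + Dice loss
#'
#' @inheritParams bce_loss
#' @param config a [loss_config()].
#' @return `lambda_bce * bce_loss + (1 - lambda_bce) * dice_loss`.
#' @export
combined_loss <- function(pred, target, config = loss_config()) {
  config$lambda_bce * bce_loss(pred, target, config$prob_clip_eps) +
    (1 - config$lambda_bce) * dice_loss(pred, target, config$smooth_eps)
}

# Gradient of the combined loss with respect to the predicted
# probabilities (same shape as pred). Used by the training loop.
combined_loss_grad <- function(pred, target, config = loss_config()) {
  pt <- loss_pair(pred, target)
  p <- pt$p; y <- pt$y
  eps <- config$prob_clip_eps
  pc <- pmin(pmax(p, eps), 1 - eps)
  g_bce <- (-(y / pc) + (1 - y) / (1 - pc)) / length(p)
  denom <- sum(p) + sum(y) + config$smooth_eps
  num <- 2 * sum(p * y) + config$smooth_eps
  g_dice <- -(2 * y * denom - num) / denom^2
  g <- config$lambda_bce * g_bce + (1 - config$lambda_bce) * g_dice
  dim(g) <- dim(p)
  g
}
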