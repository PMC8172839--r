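#' Hybrid-loss weights
#'
#' Defaults give the cross-entropy and the Dice terms equal weight:
#' alpha = 0.5 on cross-entropy, beta = gamma = 0.25 on the background
#' and foreground Dice losses.
#' @param alpha,beta,gamma non-negative weights.
#' @export
loss_weights <- function(alpha = 0.5, beta = 0.25, gamma = 0.25) {
  if (any(c(alpha, beta, gamma) < 0)) stop("loss weights must be non-negative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma), class = "loss_weights")
}

#' Soft Dice loss
#'
#' Differentiable relaxation of the Dice overlap between a posterior
#' probability map `p` and a binary ground truth `g`:
#' `1 - (2 sum(p g) + eps) / (sum(p^2) + sum(g^2) + eps)`.
#' The smoothing epsilon guards empty masks (both-empty gives 0).
#'
#' @param p numeric array/matrix of probabilities in `[0, 1]`.
#' @param g binary array of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss in `[0, 1]` (up to eps).
#' @export
dice_loss <- function(p, g, eps = 1e-6) {
  if (!all(dim_or_len(p) == dim_or_len(g))) stop("shape mismatch between p and g")
  1 - (2 * sum(p * g) + eps) / (sum(p^2) + sum(g^2) + eps)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Pixel-wise binary cross-entropy loss
#'
#' Mean over pixels of `-(g log p + (1 - g) log(1 - p))`, with `p`
#' clipped away from 0 and 1 for numerical stability.
#'
#' @inheritParams dice_loss
#' @param clip probabilities are clipped to `[clip, 1 - clip]`.
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(p, g, clip = 1e-7) {
  if (!all(dim_or_len(p) == dim_or_len(g))) stop("shape mismatch between p and g")
  p <- pmin(pmax(p, clip), 1 - clip)
  -mean(g * log(p) + (1 - g) * log(1 - p))
}

#' Hybrid segmentation loss
#'
#' `alpha * CE + beta * Dice(1 - p, 1 - g) + gamma * Dice(p, g)`:
#' cross-entropy plus Dice losses on the background and tumor
#' (foreground) channels, designed to counter the extreme class
#' imbalance of tumor pixels in whole-slide images.
#'
#' @inheritParams dice_loss
#' @param w a [loss_weights].
#' @export
hybrid_loss <- function(p, g, w = loss_weights(), eps = 1e-6) {
  if (!inherits(w, "loss_weights")) w <- do.call(loss_weights, as.list(w))
  w$alpha * cross_entropy_loss(p, g) +
    w$beta * dice_loss(1 - p, 1 - g, eps) +
    w$gamma * dice_loss(p, g, eps)
}

# gradient of the hybrid loss with respect to p (used by FCN training)
hybrid_loss_grad <- function(p, g, w = loss_weights(), eps = 1e-6, clip = 1e-7) {
  pc <- pmin(pmax(p, clip), 1 - clip)
  n <- length(p)
  g_ce <- -(g / pc - (1 - g) / (1 - pc)) / n
  dice_grad <- function(p, g) {
    num <- 2 * sum(p * g) + eps
    den <- sum(p^2) + sum(g^2) + eps
    -(2 * g) / den + num * 2 * p / den^2
  }
  w$alpha * g_ce + w$gamma * dice_grad(p, g) - w$beta * dice_grad(1 - p, 1 - g)
}
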