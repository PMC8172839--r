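#' Predictor contract
#'
#' A predictor is any object with a [predict_patch] method mapping an RGB
#' patch (`h x w x 3` array in `[0, 1]`) to a posterior probability map
#' of identical spatial dimensions, deterministically in inference mode.
#' Stitching, uncertainty and staging only rely on this contract, so a
#' full-scale convolutional backbone, the package's own trainable
#' mini-FCN ([mini_fcn]) and the deterministic mock predictors below are
#' interchangeable.
#'
#' @param predictor a predictor object.
#' @param patch RGB array.
#' @param ... optional context: `center` (a [level_point] at level 0) and
#'   `img`, supplied by the slide-inference loop; content-based
#'   predictors ignore them.
#' @return matrix of probabilities in `[0, 1]`, same `h x w` as `patch`.
#' @export
predict_patch <- function(predictor, patch, ...) UseMethod("predict_patch")

#' Constant mock predictor
#' @param value probability returned at every pixel.
#' @export
constant_predictor <- function(value) {
  stopifnot(value >= 0, value <= 1)
  structure(list(value = value), class = c("constant_predictor", "predictor"))
}

#' @export
predict_patch.constant_predictor <- function(predictor, patch, ...) {
  matrix(predictor$value, nrow(patch[, , 1]), ncol(patch[, , 1]))
}

#' Ground-truth oracle mock predictor
#'
#' Returns the crop of a known level-0 probability (or binary) map under
#' the patch footprint; out-of-bounds pixels read 0. Requires the
#' `center` context argument from the inference loop. With `noise_sd > 0`
#' deterministic pseudo-noise (seeded from the patch center) is added and
#' clipped, giving a reproducible "noisy oracle".
#'
#' @param truth0 level-0 numeric matrix in `[0, 1]`.
#' @param noise_sd Gaussian noise sd (0 = exact oracle).
#' @export
oracle_predictor <- function(truth0, noise_sd = 0) {
  structure(list(truth0 = truth0, noise_sd = noise_sd),
            class = c("oracle_predictor", "predictor"))
}

#' @export
predict_patch.oracle_predictor <- function(predictor, patch, center = NULL, ...) {
  if (is.null(center)) stop("oracle_predictor needs the patch center context")
  size <- nrow(patch[, , 1])
  t0 <- predictor$truth0
  x0 <- floor(center$x - size / 2); y0 <- floor(center$y - size / 2)
  out <- matrix(0, size, size)
  xs <- (x0 + 1):(x0 + size); ys <- (y0 + 1):(y0 + size)
  kx <- which(xs >= 1 & xs <= ncol(t0)); ky <- which(ys >= 1 & ys <= nrow(t0))
  if (length(kx) && length(ky)) out[ky, kx] <- t0[ys[ky], xs[kx]]
  if (predictor$noise_sd > 0) {
    out <- with_seed((abs(center$x) * 7919 + abs(center$y)) %% .Machine$integer.max,
                     out + rnorm(length(out), 0, predictor$noise_sd))
    out <- clip01(out)
  }
  out
}

#' Per-pixel rule predictor
#'
#' Applies a function of the three channel values at each pixel; being a
#' pointwise function of the image content it is exactly equivariant
#' under flips and right-angle rotations.
#'
#' @param fun function(r, g, b) returning probabilities, vectorized.
#' @export
pixel_predictor <- function(fun) {
  structure(list(fun = fun), class = c("pixel_predictor", "predictor"))
}

#' @export
predict_patch.pixel_predictor <- function(predictor, patch, ...) {
  p <- predictor$fun(patch[, , 1], patch[, , 2], patch[, , 3])
  matrix(clip01(p), nrow(patch[, , 1]), ncol(patch[, , 1]))
}

#' Ensemble prediction by posterior averaging
#'
#' The ensemble's prediction for a patch is the pixel-wise arithmetic
#' mean of its members' posterior probability maps.
#'
#' @param models non-empty list of predictors.
#' @inheritParams predict_patch
#' @export
ensemble_predict <- function(models, patch, ...) {
  stopifnot(length(models) >= 1)
  preds <- lapply(models, predict_patch, patch = patch, ...)
  d1 <- dim(preds[[1]])
  for (p in preds) if (!all(dim(p) == d1))
    stop("ensemble members produced maps of different dimensions")
  Reduce(`+`, preds) / length(preds)
}
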