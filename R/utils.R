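#' @useDynLib wsikit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm setNames
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate expr with a private RNG state seeded by `seed`; the global
# .Random.seed is restored afterwards so package randomness never leaks
# into (or depends on) the caller's RNG stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Block-mean reduction of a matrix by integer factor f; output dims are
# floor(dim / f), trailing rows/cols beyond the last full block dropped.
block_reduce <- function(m, f) {
  f <- as.integer(f)
  if (f == 1L) return(m)
  hk <- nrow(m) %/% f
  wk <- ncol(m) %/% f
  a <- m[seq_len(hk * f), seq_len(wk * f), drop = FALSE]
  dim(a) <- c(f, hk, f, wk)
  a <- colMeans(a)            # (hk, f, wk)
  a <- colMeans(aperm(a, c(2L, 1L, 3L)))
  a
}

block_reduce_array <- function(arr, f) {
  if (f == 1L) return(arr)
  ch <- dim(arr)[3]
  planes <- lapply(seq_len(ch), function(k) block_reduce(arr[, , k], f))
  array(unlist(planes), dim = c(dim(planes[[1]]), ch))
}

# Matrices are [row = y, col = x]; EBImage images are [x, y].
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

#' Intersection-over-union and Dice overlap of two binary masks
#'
#' Both-empty pairs score 1 by convention.
#' @param a,b binary matrices of equal shape.
#' @export
mask_iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' @rdname mask_iou
#' @export
binary_dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# Vectorised HSV -> RGB on values in [0,1]; returns 3 x n matrix like
# grDevices::rgb2hsv's layout.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  i <- i %% 6
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

rgb_array_to_hsv <- function(arr) {
  n <- prod(dim(arr)[1:2])
  m <- rbind(as.vector(arr[, , 1]), as.vector(arr[, , 2]), as.vector(arr[, , 3]))
  grDevices::rgb2hsv(m, maxColorValue = 1)
}

hsv_to_rgb_array <- function(hsv, dims) {
  m <- hsv_to_rgb(hsv[1, ], hsv[2, ], hsv[3, ])
  array(c(m[1, ], m[2, ], m[3, ]), dim = c(dims, 3))
}

# Saturation channel of an RGB array (HSV definition), in [0,1].
saturation_channel <- function(arr) {
  mx <- pmax(arr[, , 1], arr[, , 2], arr[, , 3])
  mn <- pmin(arr[, , 1], arr[, , 2], arr[, , 3])
  s <- ifelse(mx > 0, 1 - mn / mx, 0)
  matrix(s, nrow = dim(arr)[1])
}

#' Rasterize the convex hull of a set of pixels
#'
#' Computes the convex hull of the given pixel coordinates and returns a
#' binary matrix marking every pixel whose center lies inside (or on) the
#' hull polygon. Degenerate inputs (fewer than three non-collinear points)
#' mark only the input pixels themselves.
#'
#' @param xy two-column matrix of (x, y) pixel coordinates, 1-based.
#' @param dims output dimensions c(nrow, ncol).
#' @return logical matrix of dimension `dims`.
#' @export
rasterize_convex_hull <- function(xy, dims) {
  out <- matrix(FALSE, dims[1], dims[2])
  if (is.null(xy) || nrow(xy) == 0) return(out)
  xy <- unique(xy[, 1:2, drop = FALSE])
  if (nrow(xy) <= 2) {
    out[cbind(xy[, 2], xy[, 1])] <- TRUE
    return(out)
  }
  hull <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[hull, 1]; hy <- xy[hull, 2]
  if (length(hull) <= 2) {            # collinear point set
    out[cbind(xy[, 2], xy[, 1])] <- TRUE
    return(out)
  }
  xr <- range(hx); yr <- range(hy)
  xs <- xr[1]:xr[2]; ys <- yr[1]:yr[2]
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- rep(TRUE, length(px))
  n <- length(hull)
  # chull returns vertices in clockwise order for the (x, y) plane; a point
  # is inside iff every edge cross-product keeps the same (non-positive) sign.
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (px - hx[i]) * (hy[j] - hy[i]) - (py - hy[i]) * (hx[j] - hx[i])
    inside <- inside & (cr >= -1e-9)
  }
  out[cbind(py[inside], px[inside])] <- TRUE
  out
}

# population moments helpers used for feature statistics
pop_var <- function(x) if (length(x) < 2) 0 else mean((x - mean(x))^2)
pop_skew <- function(x) {
  if (length(x) < 2) return(0)
  v <- pop_var(x)
  if (v <= 0) return(0)
  mean((x - mean(x))^3) / v^1.5
}
pop_kurt <- function(x) {
  if (length(x) < 2) return(0)
  v <- pop_var(x)
  if (v <= 0) return(0)
  mean((x - mean(x))^4) / v^2 - 3
}
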