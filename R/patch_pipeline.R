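#' Augmentation parameters
#'
#' Maximum deltas follow the training recipe: brightness 64/255, contrast
#' 0.75, hue 0.25, saturation 0.04 (fractional units); each draw is
#' uniform within +/- the maximum. Geometric augmentations (flips and
#' right-angle rotations) are applied identically to patch and mask;
#' color shifts touch the patch only.
#'
#' @param flips,rot90 enable random horizontal/vertical flips and
#'   90-degree rotations.
#' @param gaussian_blur enable Gaussian blurring with sigma drawn from
#'   `[0, blur_sigma_max]`.
#' @param brightness_delta,contrast_delta,hue_delta,saturation_delta
#'   maximum absolute shifts.
#' @param blur_sigma_max upper bound of the blur sigma.
#' @param perturb_radius radius (level-0 pixels) for training-coordinate
#'   center perturbation.
#' @export
augmentation_params <- function(flips = TRUE, rot90 = TRUE,
                                gaussian_blur = FALSE,
                                brightness_delta = 64 / 255,
                                contrast_delta = 0.75, hue_delta = 0.25,
                                saturation_delta = 0.04,
                                blur_sigma_max = 1.5,
                                perturb_radius = 128L) {
  structure(as.list(environment()), class = "augmentation_params")
}

#' Extract class-balanced training patch coordinates
#'
#' Samples `n_per_class` tumor and `n_per_class` normal patch centers
#' uniformly over the eligible tissue-positive centers at the mask level,
#' mapped to level 0. A coordinate is labeled `tumor` iff its level-0
#' patch footprint contains at least one tumor pixel; candidates are
#' pre-screened with a dilated tumor mask at the mask level and then
#' verified exactly against the level-0 footprint. If a class has no
#' eligible centers the function returns fewer coordinates for it and
#' sets the `short` attribute instead of silently duplicating.
#'
#' @param img a [pyramid_image].
#' @param tissue a `tissue_mask` (any pyramid level).
#' @param tumor_mask0 level-0 binary tumor mask (may be all-zero).
#' @param n_per_class patches per class.
#' @param patch_size level-0 patch side, default 256.
#' @param seed integer seed; sampling is deterministic per seed.
#' @return data.frame with level-0 `x`, `y` (0-based centers) and `label`;
#'   attribute `short` is TRUE when a class came up short.
#' @export
extract_training_coordinates <- function(img, tissue, tumor_mask0, n_per_class,
                                         patch_size = 256L, seed = 1L) {
  stopifnot(n_per_class >= 1)
  grid <- tissue$grid > 0
  if (!any(grid)) stop("empty tissue mask: no eligible patch centers")
  f <- img$downsample_factors[tissue$level + 1L]
  has_tumor <- any(tumor_mask0 > 0)

  # prescreen at mask level: centers whose footprint MIGHT touch tumor
  if (has_tumor) {
    tum_lv <- mask_at_level(tumor_mask0, img, tissue$level)
    r_out <- ceiling((patch_size / 2) / f) + 1L
    maybe <- from_ebi(EBImage::dilate(as_ebi(tum_lv + 0), disc_brush(r_out))) > 0.5
  } else maybe <- matrix(FALSE, nrow(grid), ncol(grid))

  idx_all <- which(grid)
  idx_maybe <- which(grid & maybe)

  footprint_tumor <- function(x0, y0) {
    # exact level-0 footprint test (0-based center, 1-based matrix)
    xs <- max(1, floor(x0 - patch_size / 2) + 1):min(ncol(tumor_mask0), floor(x0 - patch_size / 2) + patch_size)
    ys <- max(1, floor(y0 - patch_size / 2) + 1):min(nrow(tumor_mask0), floor(y0 - patch_size / 2) + patch_size)
    any(tumor_mask0[ys, xs] > 0)
  }
  to_level0 <- function(idx) {
    h <- nrow(grid)
    x_lv <- (idx - 1) %/% h      # 0-based mask-level coords
    y_lv <- (idx - 1) %% h
    cbind(x = round((x_lv + 0.5) * f - 0.5), y = round((y_lv + 0.5) * f - 0.5))
  }

  with_seed(seed, {
    sample_class <- function(pool, want_tumor, n) {
      got <- matrix(numeric(0), 0, 2)
      pool <- sample(pool)           # uniform order over eligible centers
      i <- 1L
      while (nrow(got) < n && i <= length(pool)) {
        take <- pool[i:min(length(pool), i + 4L * n)]
        i <- i + length(take)
        xy <- to_level0(take)
        ok <- vapply(seq_len(nrow(xy)),
                     function(r) footprint_tumor(xy[r, 1], xy[r, 2]) == want_tumor,
                     logical(1))
        got <- rbind(got, xy[ok, , drop = FALSE])
      }
      got[seq_len(min(n, nrow(got))), , drop = FALSE]
    }
    tum_xy <- if (has_tumor) sample_class(idx_maybe, TRUE, n_per_class)
              else matrix(numeric(0), 0, 2)
    # normal candidates come from all tissue centers and are verified
    # exactly, so sampling stays uniform over the true eligible set
    norm_xy <- sample_class(idx_all, FALSE, n_per_class)
    short <- nrow(tum_xy) < n_per_class || nrow(norm_xy) < n_per_class
    if (short)
      warning("fewer eligible centers than requested for at least one class")
    out <- data.frame(x = c(tum_xy[, 1], norm_xy[, 1]),
                      y = c(tum_xy[, 2], norm_xy[, 2]),
                      label = c(rep("tumor", nrow(tum_xy)),
                                rep("normal", nrow(norm_xy))),
                      stringsAsFactors = FALSE)
    attr(out, "short") <- short
    out
  })
}

#' Randomly perturb a patch center within a disk
#'
#' Offsets the center by a draw uniform over the disk of the given radius
#' (so the expected offset magnitude is 2r/3), rounded to integer pixels
#' without ever exceeding the radius, and clipped to the slide bounds.
#'
#' @param x,y level-0 center (0-based).
#' @param radius maximum offset in pixels (default 128).
#' @param seed integer seed.
#' @param width0,height0 slide bounds for clipping (optional).
#' @return named vector c(x, y).
#' @export
perturb_coordinate <- function(x, y, radius = 128, seed = 1L,
                               width0 = Inf, height0 = Inf) {
  stopifnot(radius >= 0)
  with_seed(seed, {
    r <- radius * sqrt(runif(1))
    phi <- runif(1, 0, 2 * pi)
    dx <- round(r * cos(phi)); dy <- round(r * sin(phi))
    if (dx^2 + dy^2 > radius^2) {    # rounding pushed past the rim
      dx <- trunc(r * cos(phi)); dy <- trunc(r * sin(phi))
    }
    c(x = min(max(x + dx, 0), width0 - 1),
      y = min(max(y + dy, 0), height0 - 1))
  })
}

rot90_cw <- function(m, k = 1L) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}
apply_plane <- function(arr, fn) {
  planes <- lapply(seq_len(dim(arr)[3]), function(ch) fn(arr[, , ch]))
  array(unlist(planes), dim = c(dim(planes[[1]]), dim(arr)[3]))
}

#' Augment a patch and its mask
#'
#' Geometric transforms (flips, right-angle rotations) are applied
#' identically to patch and mask; brightness/contrast/hue/saturation
#' shifts, each drawn uniformly within its +/- maximum delta, and the
#' optional Gaussian blur apply to the patch only. Output pixel values
#' are clipped to `[0, 1]`. (Normalization for the network input is a
#' separate step, see [normalize_patch].)
#'
#' @param patch `h x w x 3` array in `[0, 1]`.
#' @param mask `h x w` binary matrix.
#' @param params an [augmentation_params].
#' @param seed integer seed; identical seed gives identical draws.
#' @return list(patch, mask).
#' @export
augment_patch <- function(patch, mask, params = augmentation_params(), seed = 1L) {
  stopifnot(all(dim(patch)[1:2] == dim(mask)))
  with_seed(seed, {
    if (isTRUE(params$flips)) {
      if (runif(1) < 0.5) { patch <- apply_plane(patch, function(m) m[, ncol(m):1]); mask <- mask[, ncol(mask):1] }
      if (runif(1) < 0.5) { patch <- apply_plane(patch, function(m) m[nrow(m):1, ]); mask <- mask[nrow(mask):1, ] }
    }
    if (isTRUE(params$rot90)) {
      k <- sample(0:3, 1)
      if (k > 0) { patch <- apply_plane(patch, function(m) rot90_cw(m, k)); mask <- rot90_cw(mask, k) }
    }
    b <- runif(1, -params$brightness_delta, params$brightness_delta)
    cdel <- runif(1, -params$contrast_delta, params$contrast_delta)
    hdel <- runif(1, -params$hue_delta, params$hue_delta)
    sdel <- runif(1, -params$saturation_delta, params$saturation_delta)
    if (b != 0) patch <- patch + b
    if (cdel != 0) { mu <- mean(patch); patch <- (patch - mu) * (1 + cdel) + mu }
    if (hdel != 0 || sdel != 0) {
      hsv <- rgb_array_to_hsv(clip01(patch))
      hsv[1, ] <- (hsv[1, ] + hdel) %% 1
      hsv[2, ] <- pmin(pmax(hsv[2, ] + sdel, 0), 1)
      patch <- hsv_to_rgb_array(hsv, dim(patch)[1:2])
    }
    if (isTRUE(params$gaussian_blur)) {
      sigma <- runif(1, 0, params$blur_sigma_max)
      if (sigma > 0.05)
        patch <- apply_plane(patch, function(m) from_ebi(EBImage::gblur(as_ebi(m), sigma)))
    }
    list(patch = clip01(patch), mask = mask)
  })
}

#' Shift a hue/saturation pair deterministically (no random draws)
#'
#' Helper exposing the color model used by [augment_patch] so exact
#' round-trip behavior can be exercised.
#' @param patch RGB array in `[0, 1]`.
#' @param hue_shift,sat_shift additive shifts; hue wraps modulo 1.
#' @export
shift_hsv <- function(patch, hue_shift = 0, sat_shift = 0) {
  hsv <- rgb_array_to_hsv(patch)
  hsv[1, ] <- (hsv[1, ] + hue_shift) %% 1
  hsv[2, ] <- pmin(pmax(hsv[2, ] + sat_shift, 0), 1)
  hsv_to_rgb_array(hsv, dim(patch)[1:2])
}

#' Normalize a patch for network input
#'
#' Per-channel standardization `(x - mean) / sd` on the `[0, 1]` scale;
#' the constants travel with the trained model bundle.
#' @param patch RGB array in `[0, 1]`.
#' @param mean,sd length-3 per-channel constants.
#' @export
normalize_patch <- function(patch, mean = c(0.5, 0.5, 0.5), sd = c(0.25, 0.25, 0.25)) {
  for (ch in 1:3) patch[, , ch] <- (patch[, , ch] - mean[ch]) / sd[ch]
  patch
}

#' Build the uniform inference patch-sampling grid
#'
#' Lays a level-0 lattice of candidate centers spaced by `stride`,
#' starting at `floor(patch_size/2)` so every footprint fits the slide,
#' and keeps a center iff its pixel at the tissue-mask level is tissue —
#' non-tissue patches are discarded to save computation. Centers are
#' returned in row-major order.
#'
#' @param img a [pyramid_image].
#' @param tissue a `tissue_mask`.
#' @param patch_size level-0 patch side (default 1024).
#' @param stride level-0 spacing between consecutive centers; must be in
#'   `[1, patch_size]` (stride = patch_size/2 gives the 50% overlap that
#'   balances accuracy and cost).
#' @return a `patch_grid`: list with `centers` data.frame (0-based level-0
#'   x, y), `patch_size`, `stride`, `grid_level`; attribute `empty` set
#'   when the mask had no tissue.
#' @export
build_inference_grid <- function(img, tissue, patch_size = 1024L, stride = 512L) {
  stopifnot(stride >= 1, stride <= patch_size)
  f <- img$downsample_factors[tissue$level + 1L]
  xs <- seq(floor(patch_size / 2), img$width0 - ceiling(patch_size / 2), by = stride)
  ys <- seq(floor(patch_size / 2), img$height0 - ceiling(patch_size / 2), by = stride)
  if (length(xs) == 0) xs <- floor(img$width0 / 2)
  if (length(ys) == 0) ys <- floor(img$height0 / 2)
  cx <- rep(xs, times = length(ys))
  cy <- rep(ys, each = length(xs))       # row-major: y outer, x inner
  mx <- pmin(pmax(round(cx / f), 0), ncol(tissue$grid) - 1L)
  my <- pmin(pmax(round(cy / f), 0), nrow(tissue$grid) - 1L)
  keep <- tissue$grid[cbind(my + 1L, mx + 1L)] > 0
  empty <- !any(keep)
  if (empty) warning("empty tissue mask: inference grid has no centers")
  structure(list(centers = data.frame(x = cx[keep], y = cy[keep]),
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 grid_level = tissue$level),
            class = "patch_grid", empty = empty)
}

#' Construct a patch grid from explicit centers
#'
#' Low-level constructor used when the sampling lattice comes from
#' somewhere other than [build_inference_grid] (e.g. synthetic stitching
#' scenarios).
#' @param centers data.frame with 0-based level-0 `x`, `y` columns.
#' @param patch_size,stride level-0 geometry.
#' @param grid_level level the tissue screening happened at (metadata).
#' @export
patch_grid <- function(centers, patch_size, stride, grid_level = 0L) {
  stopifnot(is.data.frame(centers), all(c("x", "y") %in% names(centers)))
  structure(list(centers = centers, patch_size = as.integer(patch_size),
                 stride = as.integer(stride), grid_level = as.integer(grid_level)),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("patch_grid: %d centers, patch %d, stride %d (grid level %s)\n",
              nrow(x$centers), x$patch_size, x$stride, format(x$grid_level)))
  invisible(x)
}
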