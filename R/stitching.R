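#' Stitch per-patch probability maps into a slide heatmap
#'
#' Each patch map is accumulated into level-0 sum and coverage-count
#' grids; the final probability at a pixel is the arithmetic mean of all
#' patch predictions covering it (which removes seams between overlapping
#' patches) and 0 where no patch covered it. When `out_level > 0` the sum
#' and count grids are block-reduced first and divided afterwards, so
#' overlap averaging and downscaling commute.
#'
#' @param grid a `patch_grid` (see [build_inference_grid]).
#' @param patch_probs list of probability matrices, one per grid center,
#'   each `patch_size x patch_size`.
#' @param width0,height0 level-0 slide dimensions.
#' @param out_level level at which to materialize the heatmap (0 = full
#'   resolution).
#' @param factor downsample factor per level step (used when
#'   `out_level > 0`).
#' @return a `stitched_heatmap`: list with `prob` and `count` grids and
#'   `level`.
#' @export
stitch_heatmap <- function(grid, patch_probs, width0, height0,
                           out_level = 0L, factor = 4L) {
  n <- nrow(grid$centers)
  if (length(patch_probs) != n)
    stop("number of probability maps does not match number of grid centers")
  ps <- grid$patch_size
  s <- matrix(0, height0, width0)
  cnt <- matrix(0L, height0, width0)
  for (i in seq_len(n)) {
    p <- patch_probs[[i]]
    x0 <- floor(grid$centers$x[i] - ps / 2)   # 0-based top-left
    y0 <- floor(grid$centers$y[i] - ps / 2)
    xs <- (x0 + 1):(x0 + ps); ys <- (y0 + 1):(y0 + ps)
    kx <- which(xs >= 1 & xs <= width0); ky <- which(ys >= 1 & ys <= height0)
    if (!length(kx) || !length(ky)) next
    s[ys[ky], xs[kx]] <- s[ys[ky], xs[kx]] + p[ky, kx]
    cnt[ys[ky], xs[kx]] <- cnt[ys[ky], xs[kx]] + 1L
  }
  if (out_level > 0) {
    f <- as.integer(factor)^out_level
    s <- block_reduce(s, f) * f^2        # block sums
    cnt <- block_reduce(cnt + 0, f) * f^2
  }
  prob <- ifelse(cnt > 0, s / pmax(cnt, 1), 0)
  structure(list(prob = prob, count = cnt, level = as.integer(out_level)),
            class = "stitched_heatmap")
}

#' @export
print.stitched_heatmap <- function(x, ...) {
  cat(sprintf("stitched_heatmap: %d x %d at level %d, covered %.1f%%, range [%.3f, %.3f]\n",
              nrow(x$prob), ncol(x$prob), x$level, 100 * mean(x$count > 0),
              min(x$prob), max(x$prob)))
  invisible(x)
}

#' Run patch-based slide inference
#'
#' Composes the full inference pipeline: tissue mask at the mask level,
#' uniform patch sampling grid over tissue, per-patch ensemble prediction
#' (posterior averaging), and overlap-averaged stitching into a heatmap
#' materialized at `out_level`. Batch/grid order does not affect the
#' output.
#'
#' @param img a [pyramid_image].
#' @param models list of predictors (ensemble members).
#' @param patch_size,stride level-0 grid geometry (defaults 1024 / 512,
#'   i.e. 50% overlap).
#' @param params a [mask_params] for tissue detection.
#' @param mask_level tissue-mask level; default [default_mask_level].
#' @param out_level heatmap level; default = mask level.
#' @param tissue precomputed `tissue_mask` (skips mask computation).
#' @return list with `heatmap` (a `stitched_heatmap`) and `tissue`.
#' @export
run_slide_inference <- function(img, models, patch_size = 1024L, stride = 512L,
                                params = mask_params(), mask_level = NULL,
                                out_level = NULL, tissue = NULL) {
  if (is.null(tissue)) tissue <- tissue_mask_for_slide(img, params, mask_level)
  if (is.null(out_level)) out_level <- tissue$level
  grid <- build_inference_grid(img, tissue, patch_size, stride)
  probs <- lapply(seq_len(nrow(grid$centers)), function(i) {
    ctr <- level_point(grid$centers$x[i], grid$centers$y[i], 0L)
    patch <- read_region(img, ctr, patch_size, level = 0L)
    ensemble_predict(models, patch, center = ctr, img = img)
  })
  hm <- stitch_heatmap(grid, probs, img$width0, img$height0,
                       out_level = out_level,
                       factor = infer_factor_step(img))
  list(heatmap = hm, tissue = tissue, grid = grid)
}

infer_factor_step <- function(img) {
  if (n_levels(img) < 2) return(4L)
  as.integer(round(img$downsample_factors[2] / img$downsample_factors[1]))
}

#' Write a heatmap as an 8-bit PNG (value = round(255 p)) or 32-bit TIFF
#' @param hm a `stitched_heatmap`.
#' @param path output path; `.png` gives the 8-bit rendering, `.tif(f)`
#'   a lossless 32-bit float TIFF.
#' @export
write_heatmap <- function(hm, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(round(255 * hm$prob) / 255, path)
  } else {
    tiff::writeTIFF(hm$prob, path, bits.per.sample = 32L)
  }
  invisible(path)
}
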