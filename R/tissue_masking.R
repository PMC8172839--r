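#' Tissue masking parameters
#'
#' @param closing_radius,opening_radius disc radii (pixels at the mask
#'   level) for the binary closing-then-opening cleanup; 0 disables a
#'   stage.
#' @param fill_holes fill enclosed background holes after morphology.
#' @param camelyon_preprocess apply [preprocess_camelyon] before
#'   thresholding (black-region replacement + 7x7 median blur).
#' @param black_threshold per-channel level below which a pixel counts as
#'   black for the preprocessing step (fraction of full scale).
#' @param sat_epsilon saturation range below which the histogram is
#'   declared degenerate and an empty mask is returned with a warning flag.
#' @export
mask_params <- function(closing_radius = 2L, opening_radius = 2L,
                        fill_holes = FALSE, camelyon_preprocess = FALSE,
                        black_threshold = 10 / 255, sat_epsilon = 1e-3) {
  structure(as.list(environment()), class = "mask_params")
}

disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")

#' Replace black scanner regions with white and median-blur
#'
#' Pre-cleaning for slides whose background contains black scanner
#' artifacts that would corrupt the saturation histogram: pixels with all
#' three channels below `black_threshold` are replaced by white, then a
#' 7x7 median blur smooths tissue and removes noise at the tissue/glass
#' boundary while preserving edges.
#'
#' @param rgb an `h x w x 3` array in `[0, 1]`.
#' @param black_threshold per-channel black level (fraction of full scale).
#' @param kernel odd median window side, default 7.
#' @return RGB array of the same shape.
#' @export
preprocess_camelyon <- function(rgb, black_threshold = 10 / 255, kernel = 7L) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  black <- rgb[, , 1] < black_threshold & rgb[, , 2] < black_threshold &
    rgb[, , 3] < black_threshold
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[black] <- 1
    rgb[, , ch] <- plane
  }
  half <- (as.integer(kernel) - 1L) %/% 2L
  if (half > 0) {
    for (ch in 1:3)
      rgb[, , ch] <- from_ebi(EBImage::medianFilter(as_ebi(rgb[, , ch]), half))
  }
  rgb
}

#' Segment tissue from glass by Otsu thresholding of HSV saturation
#'
#' The RGB raster (a low-resolution pyramid level) is converted to HSV;
#' Otsu's threshold is computed on the 8-bit (256-bin) saturation
#' histogram, pixels above the threshold become tissue, and a binary
#' closing-then-opening with disc structuring elements cleans small gaps
#' and specks so patches at tissue borders are extracted properly. A
#' degenerate saturation histogram (range below `sat_epsilon`, e.g. a
#' pure-glass image) yields an empty mask with the `degenerate` flag set.
#'
#' @param rgb an `h x w x 3` array in `[0, 1]`.
#' @param params a [mask_params].
#' @param level pyramid level the raster came from (metadata echo).
#' @return a `tissue_mask`: list with binary `grid`, `level`, Otsu
#'   `threshold` and `degenerate` flag.
#' @export
compute_tissue_mask <- function(rgb, params = mask_params(), level = NA_integer_) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("expected a 3-channel RGB raster")
  if (isTRUE(params$camelyon_preprocess))
    rgb <- preprocess_camelyon(rgb, params$black_threshold)
  s <- saturation_channel(rgb)
  if (diff(range(s)) < params$sat_epsilon) {
    warning("degenerate saturation histogram; returning empty tissue mask")
    return(structure(list(grid = matrix(0L, nrow(s), ncol(s)), level = level,
                          threshold = NA_real_, degenerate = TRUE),
                     class = "tissue_mask"))
  }
  thr <- EBImage::otsu(as_ebi(s), range = c(0, 1), levels = 256)
  m <- s > thr
  m <- cleanup_mask(m, params)
  structure(list(grid = m + 0L, level = level, threshold = thr,
                 degenerate = FALSE),
            class = "tissue_mask")
}

# closing then opening (disc brushes), optional hole filling
cleanup_mask <- function(m, params) {
  im <- as_ebi(m + 0)
  if (params$closing_radius > 0)
    im <- EBImage::closing(im, disc_brush(params$closing_radius))
  if (params$opening_radius > 0)
    im <- EBImage::opening(im, disc_brush(params$opening_radius))
  if (isTRUE(params$fill_holes)) im <- EBImage::fillHull(im)
  from_ebi(im) > 0.5
}

#' Construct a tissue mask from an explicit binary grid
#'
#' Low-level constructor for masks that come from ground truth or from
#' disk rather than from [compute_tissue_mask].
#' @param grid binary matrix.
#' @param level pyramid level the grid lives at.
#' @export
tissue_mask <- function(grid, level = 0L) {
  structure(list(grid = (grid > 0) + 0L, level = as.integer(level),
                 threshold = NA_real_, degenerate = FALSE),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("tissue_mask: %d x %d at level %s, %.1f%% tissue%s\n",
              nrow(x$grid), ncol(x$grid), format(x$level),
              100 * mean(x$grid > 0),
              if (x$degenerate) " [degenerate histogram]" else ""))
  invisible(x)
}

#' Compute the tissue mask of a pyramidal slide at its mask level
#'
#' Convenience wrapper: picks the mask level with [default_mask_level]
#' (unless given) and runs [compute_tissue_mask] on that pyramid level.
#'
#' @param img a [pyramid_image].
#' @param params a [mask_params].
#' @param level mask level; defaults to the level whose longer side is
#'   nearest 2000 px.
#' @export
tissue_mask_for_slide <- function(img, params = mask_params(), level = NULL) {
  if (is.null(level)) level <- default_mask_level(img)
  compute_tissue_mask(level_raster(img, level), params, level = level)
}

#' Write a tissue mask as an 8-bit PNG with values {0, 255}
#' @param mask a `tissue_mask`.
#' @param path output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  g <- if (inherits(mask, "tissue_mask")) mask$grid else mask
  png::writePNG((g > 0) + 0, path)
  invisible(path)
}
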