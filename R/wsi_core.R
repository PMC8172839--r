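#' Level-addressable pyramidal image
#'
#' A `pyramid_image` holds an ordered list of RGB rasters (level 0 is the
#' highest resolution) together with per-level downsample factors and the
#' physical resolution at level 0 (microns per pixel). It is the in-memory
#' model of a whole-slide image used throughout the pipeline; any reader
#' that exposes per-level dimensions and region reads can populate it.
#'
#' Rasters are arrays `[row, col, channel]` with values in `[0, 1]`.
#' Coordinates are 0-based with `x` = column and `y` = row.
#'
#' @param levels list of RGB arrays, highest resolution first.
#' @param mpp0 microns per pixel at level 0.
#' @param downsample_factors numeric vector of per-level factors; inferred
#'   from the level widths when `NULL`. Factor 1 at level 0, strictly
#'   increasing.
#' @return an object of class `pyramid_image`.
#' @export
pyramid_image <- function(levels, mpp0 = 0.25, downsample_factors = NULL) {
  stopifnot(is.list(levels), length(levels) >= 1)
  for (lv in levels) {
    if (length(dim(lv)) != 3 || dim(lv)[3] != 3)
      stop("each level must be an h x w x 3 RGB array")
  }
  w0 <- ncol(levels[[1]][, , 1]); h0 <- nrow(levels[[1]][, , 1])
  if (is.null(downsample_factors))
    downsample_factors <- vapply(levels, function(lv) w0 / ncol(lv[, , 1]), 0)
  if (abs(downsample_factors[1] - 1) > 1e-9)
    stop("downsample factor at level 0 must be 1")
  if (length(downsample_factors) > 1 && any(diff(downsample_factors) <= 0))
    stop("downsample factors must strictly increase with level")
  for (k in seq_along(levels)) {
    f <- downsample_factors[k]
    dk <- dim(levels[[k]])
    if (abs(dk[1] - h0 / f) > 1 + 1e-9 || abs(dk[2] - w0 / f) > 1 + 1e-9)
      stop(sprintf("level %d dimensions inconsistent with its factor", k - 1L))
  }
  structure(list(levels = levels,
                 downsample_factors = as.numeric(downsample_factors),
                 mpp0 = mpp0, width0 = w0, height0 = h0),
            class = "pyramid_image")
}

#' @export
print.pyramid_image <- function(x, ...) {
  cat(sprintf("pyramid_image: %d x %d px at level 0, %.3g microns/px, %d levels\n",
              x$width0, x$height0, x$mpp0, n_levels(x)))
  for (k in seq_len(n_levels(x)))
    cat(sprintf("  level %d: %d x %d (factor %.4g)\n", k - 1L,
                level_width(x, k - 1L), level_height(x, k - 1L),
                x$downsample_factors[k]))
  invisible(x)
}

#' @rdname pyramid_image
#' @param img a `pyramid_image`.
#' @export
n_levels <- function(img) length(img$levels)

#' @rdname pyramid_image
#' @param level 0-based pyramid level.
#' @export
level_width <- function(img, level) ncol(img$levels[[level + 1L]][, , 1])

#' @rdname pyramid_image
#' @export
level_height <- function(img, level) nrow(img$levels[[level + 1L]][, , 1])

#' @rdname pyramid_image
#' @export
level_raster <- function(img, level) {
  check_level(img, level)
  img$levels[[level + 1L]]
}

#' Microns per pixel at a pyramid level
#' @inheritParams level_raster
#' @export
mpp_at_level <- function(img, level) {
  check_level(img, level)
  img$mpp0 * img$downsample_factors[level + 1L]
}

check_level <- function(img, level) {
  if (length(level) != 1 || level < 0 || level >= n_levels(img))
    stop(sprintf("invalid level %s; available levels: %s", format(level),
                 paste(seq_len(n_levels(img)) - 1L, collapse = ", ")))
  invisible(level)
}

#' A pixel coordinate at a pyramid level
#'
#' 0-based, `x` = column, `y` = row.
#' @param x,y integer pixel coordinates.
#' @param level 0-based pyramid level the coordinates refer to.
#' @export
level_point <- function(x, y, level = 0L) {
  structure(list(x = x, y = y, level = as.integer(level)), class = "level_point")
}

#' Map a point between pyramid levels
#'
#' Coordinates are rescaled by the ratio of downsample factors and rounded
#' to the nearest integer pixel. The round trip level 0 -> k -> 0 is exact
#' to within half the level-k downsample factor per axis.
#'
#' @param img a [pyramid_image].
#' @param p a [level_point].
#' @param to_level target 0-based level.
#' @return a [level_point] at `to_level`.
#' @export
map_point <- function(img, p, to_level) {
  check_level(img, p$level); check_level(img, to_level)
  r <- img$downsample_factors[p$level + 1L] / img$downsample_factors[to_level + 1L]
  level_point(round(p$x * r), round(p$y * r), to_level)
}

#' Read a square region from a pyramid level
#'
#' The region is addressed by its center, given at level 0, and extracted
#' at the requested level. Pixels falling outside the slide are filled
#' with white (glass background), so out-of-bounds reads can never create
#' phantom tissue.
#'
#' @param img a [pyramid_image].
#' @param center a [level_point] at level 0 (or a length-2 numeric `c(x, y)`).
#' @param size side of the square region, in pixels at `level`.
#' @param level 0-based pyramid level to read at.
#' @return a `size x size x 3` RGB array.
#' @export
read_region <- function(img, center, size, level = 0L) {
  stopifnot(size > 0)
  check_level(img, level)
  if (!inherits(center, "level_point")) center <- level_point(center[1], center[2], 0L)
  if (center$level != 0L) stop("region centers are addressed at level 0")
  c_lv <- map_point(img, center, level)
  x0 <- floor(c_lv$x - size / 2)      # top-left, 0-based
  y0 <- floor(c_lv$y - size / 2)
  lv <- img$levels[[level + 1L]]
  h <- nrow(lv[, , 1]); w <- ncol(lv[, , 1])
  out <- array(1, dim = c(size, size, 3))
  xs <- (x0 + 1):(x0 + size)          # 1-based source columns
  ys <- (y0 + 1):(y0 + size)
  keep_x <- which(xs >= 1 & xs <= w)
  keep_y <- which(ys >= 1 & ys <= h)
  if (length(keep_x) && length(keep_y))
    out[keep_y, keep_x, ] <- lv[ys[keep_y], xs[keep_x], , drop = FALSE]
  out
}

#' Write a pyramid as a directory of PNG levels
#'
#' Writes `level_0.png` ... `level_k.png` plus a `slide.json` sidecar with
#' the downsample factors and level-0 resolution.
#'
#' @param img a [pyramid_image].
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_pyramid <- function(img, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(n_levels(img)))
    png::writePNG(img$levels[[k]], file.path(path, sprintf("level_%d.png", k - 1L)))
  meta <- list(downsample_factors = img$downsample_factors, mpp0 = img$mpp0,
               width0 = img$width0, height0 = img$height0)
  jsonlite::write_json(meta, file.path(path, "slide.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pyramidal slide
#'
#' Accepts either a directory of per-level PNGs with a `slide.json` sidecar
#' (as written by [write_pyramid]) or a standard multi-page pyramidal TIFF
#' (one page per level, highest resolution first).
#'
#' @param path slide directory or TIFF file.
#' @param mpp0 microns per pixel at level 0; only used for TIFF input
#'   (the PNG sidecar stores it).
#' @return a [pyramid_image].
#' @export
read_pyramid <- function(path, mpp0 = 0.25) {
  if (dir.exists(path)) {
    meta <- jsonlite::read_json(file.path(path, "slide.json"), simplifyVector = TRUE)
    files <- file.path(path, sprintf("level_%d.png", seq_along(meta$downsample_factors) - 1L))
    levels <- lapply(files, function(f) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
      a[, , 1:3, drop = FALSE]
    })
    pyramid_image(levels, mpp0 = meta$mpp0, downsample_factors = meta$downsample_factors)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    levels <- lapply(pages, function(a) {
      if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
      a[, , 1:3, drop = FALSE]
    })
    o <- order(vapply(levels, function(a) -ncol(a[, , 1]), 0))
    pyramid_image(levels[o], mpp0 = mpp0)
  } else stop("slide path must be a PNG-pyramid directory or a .tif/.tiff file")
}

#' Write a pyramid as a multi-page TIFF
#' @inheritParams write_pyramid
#' @export
write_pyramid_tiff <- function(img, path) {
  tiff::writeTIFF(img$levels, path, bits.per.sample = 8L)
  invisible(path)
}

#' Build a pyramid from a level-0 raster by block-mean reduction
#'
#' @param base level-0 RGB array.
#' @param n_levels number of pyramid levels.
#' @param factor_step multiplicative downsample step between levels.
#' @param mpp0 microns per pixel at level 0.
#' @export
build_pyramid <- function(base, n_levels = 3L, factor_step = 4L, mpp0 = 0.25) {
  levels <- vector("list", n_levels)
  levels[[1]] <- base
  for (k in 2:n_levels)
    levels[[k]] <- block_reduce_array(levels[[k - 1]], factor_step)
  pyramid_image(levels, mpp0 = mpp0,
                downsample_factors = factor_step^(seq_len(n_levels) - 1))
}

#' Default mask level: the level whose longer side is nearest a target size
#'
#' Tissue masking and heatmap materialization happen at a reduced level;
#' by default the one whose longer side is closest to `target` pixels.
#'
#' @inheritParams level_raster
#' @param target desired longer-side size in pixels.
#' @export
default_mask_level <- function(img, target = 2000) {
  sides <- vapply(seq_len(n_levels(img)) - 1L,
                  function(k) max(level_width(img, k), level_height(img, k)), 0)
  which.min(abs(sides - target)) - 1L
}
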