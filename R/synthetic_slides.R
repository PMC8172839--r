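#' Specification for a synthetic H&E-like slide
#'
#' The generator emulates the gross appearance of a stained histology
#' slide at desk scale: white glass background, elliptical pink/purple
#' tissue blobs with texture noise, darker purple "tumor" regions strictly
#' inside tissue, an optional black scanner-border artifact, and a
#' >= 3-level image pyramid with factor-4 steps. Ground-truth tissue,
#' viable-tumor and whole-tumor masks are emitted alongside the pixels so
#' every downstream stage can be tested without slide downloads.
#'
#' @param width0,height0 level-0 dimensions in pixels (>= 256).
#' @param n_tissue_blobs number of elliptical tissue blobs.
#' @param n_tumor_regions number of tumor regions (0 for a negative slide).
#' @param tumor_size_range c(min, max) tumor major-axis length in level-0
#'   pixels.
#' @param blob_axis_frac c(min, max) tissue-blob semi-axis as a fraction of
#'   the smaller slide side.
#' @param blob_aspect_range,tumor_aspect_range c(min, max) minor/major
#'   semi-axis ratio for tissue blobs and tumor regions (`c(1, 1)` gives
#'   circles).
#' @param mpp0 microns per pixel at level 0.
#' @param add_black_border add a black border band emulating the scanner
#'   artifact seen on some slides.
#' @param stain_jitter stain variability in [0, 1]; scales per-blob color
#'   jitter.
#' @param n_levels,factor_step pyramid geometry.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return a `synthetic_slide_spec` list.
#' @export
synthetic_slide_spec <- function(width0 = 1024, height0 = 1024,
                                 n_tissue_blobs = 3, n_tumor_regions = 2,
                                 tumor_size_range = c(80, 200),
                                 blob_axis_frac = c(0.12, 0.22),
                                 blob_aspect_range = c(0.7, 1),
                                 tumor_aspect_range = c(0.65, 0.95),
                                 mpp0 = 0.25, add_black_border = FALSE,
                                 stain_jitter = 0.3, n_levels = 3L,
                                 factor_step = 4L, seed = 1L) {
  stopifnot(width0 >= 256, height0 >= 256, n_tissue_blobs >= 1,
            n_tumor_regions >= 0, n_levels >= 3,
            stain_jitter >= 0, stain_jitter <= 1,
            length(tumor_size_range) == 2,
            tumor_size_range[1] <= tumor_size_range[2])
  structure(as.list(environment()), class = "synthetic_slide_spec")
}

# filled rotated-ellipse mask; cx, cy 1-based pixel centers
ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  x <- matrix(rep(seq_len(w), each = h), h) - cx
  y <- matrix(rep(seq_len(h), times = w), h) - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic slide
#'
#' @param spec a [synthetic_slide_spec].
#' @return a `synthetic_slide`: list with `image` (a [pyramid_image]),
#'   level-0 logical `tissue_mask`, `tumor_mask` (viable tumor) and
#'   `whole_tumor_mask` (convex envelope of the tumor nests clipped to
#'   tissue), and the `spec` echo.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  with_seed(spec$seed, {
    h <- spec$height0; w <- spec$width0
    margin <- round(0.06 * min(h, w))
    border_w <- if (spec$add_black_border) round(0.02 * min(h, w)) else 0L

    # tissue blobs
    tissue <- matrix(FALSE, h, w)
    blob_params <- vector("list", spec$n_tissue_blobs)
    axr <- spec$blob_axis_frac * min(h, w)
    for (i in seq_len(spec$n_tissue_blobs)) {
      A <- runif(1, axr[1], axr[2])
      B <- runif(1, spec$blob_aspect_range[1], spec$blob_aspect_range[2]) * A
      lo_x <- margin + border_w + A; hi_x <- w - margin - A
      lo_y <- margin + border_w + A; hi_y <- h - margin - A
      if (hi_x <= lo_x || hi_y <= lo_y)
        stop("tissue blobs do not fit the slide; reduce blob_axis_frac")
      cx <- runif(1, lo_x, hi_x); cy <- runif(1, lo_y, hi_y)
      th <- runif(1, 0, pi)
      blob_params[[i]] <- list(cx = cx, cy = cy, A = A, B = B, th = th)
      tissue <- tissue | ellipse_mask(h, w, cx, cy, A, B, th)
    }

    # tumor regions, each strictly inside one blob
    tumor <- matrix(FALSE, h, w)
    if (spec$n_tumor_regions > 0) {
      for (i in seq_len(spec$n_tumor_regions)) {
        bp <- blob_params[[((i - 1) %% spec$n_tissue_blobs) + 1]]
        L <- runif(1, spec$tumor_size_range[1], spec$tumor_size_range[2])
        a <- L / 2
        b <- a * runif(1, spec$tumor_aspect_range[1], spec$tumor_aspect_range[2])
        if (a >= min(bp$A, bp$B) * 0.9)
          stop("tumor_size_range exceeds tissue blob size")
        # place the tumor center inside the blob shrunk by the tumor's
        # bounding radius so the region cannot cross the blob boundary
        sA <- bp$A - a; sB <- bp$B - a
        r <- sqrt(runif(1)); phi <- runif(1, 0, 2 * pi)
        u <- r * cos(phi) * sA * 0.95; v <- r * sin(phi) * sB * 0.95
        cx <- bp$cx + u * cos(bp$th) - v * sin(bp$th)
        cy <- bp$cy + u * sin(bp$th) + v * cos(bp$th)
        tumor <- tumor | ellipse_mask(h, w, cx, cy, a, b, runif(1, 0, pi))
      }
      tumor <- tumor & tissue
    }

    # whole tumor = convex envelope of the viable nests, clipped to tissue
    whole <- if (any(tumor)) {
      idx <- which(tumor)
      xy <- cbind(((idx - 1) %/% h) + 1L, ((idx - 1) %% h) + 1L)
      rasterize_convex_hull(xy, c(h, w)) & tissue
    } else matrix(FALSE, h, w)

    # paint the slide
    n <- h * w
    base <- array(runif(3 * n, 0.955, 1.0), dim = c(h, w, 3))
    tissue_col <- c(0.87, 0.58, 0.77)    # H&E pink/purple, saturation ~0.33
    tumor_col <- c(0.48, 0.28, 0.56)     # darker nuclei-dense purple
    for (i in seq_len(spec$n_tissue_blobs)) {
      bp <- blob_params[[i]]
      bm <- ellipse_mask(h, w, bp$cx, bp$cy, bp$A, bp$B, bp$th)
      jit <- spec$stain_jitter * runif(3, -0.06, 0.06)
      for (ch in 1:3) {
        plane <- base[, , ch]
        plane[bm] <- tissue_col[ch] + jit[ch]
        base[, , ch] <- plane
      }
    }
    if (any(tumor)) {
      for (ch in 1:3) {
        plane <- base[, , ch]
        plane[tumor] <- tumor_col[ch]
        base[, , ch] <- plane
      }
    }
    # texture noise inside tissue
    tn <- sum(tissue)
    if (tn > 0) {
      for (ch in 1:3) {
        plane <- base[, , ch]
        plane[tissue] <- plane[tissue] + rnorm(tn, 0, 0.02)
        base[, , ch] <- plane
      }
    }
    if (border_w > 0) {
      base[seq_len(border_w), , ] <- 0.02
      base[, seq_len(border_w), ] <- 0.02
    }
    base <- clip01(base)

    img <- build_pyramid(base, n_levels = spec$n_levels,
                         factor_step = spec$factor_step, mpp0 = spec$mpp0)
    structure(list(image = img, tissue_mask = tissue, tumor_mask = tumor,
                   whole_tumor_mask = whole, spec = spec),
              class = "synthetic_slide")
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("synthetic_slide: %d x %d, tissue %.1f%%, tumor %.2f%%\n",
              x$spec$width0, x$spec$height0,
              100 * mean(x$tissue_mask), 100 * mean(x$tumor_mask)))
  invisible(x)
}

#' Downsample a level-0 binary mask to a pyramid level
#'
#' Block-mean reduction followed by a 0.5 majority threshold.
#'
#' @param mask level-0 logical/0-1 matrix.
#' @param img the [pyramid_image] the mask belongs to.
#' @param level target level.
#' @export
mask_at_level <- function(mask, img, level) {
  check_level(img, level)
  f <- img$downsample_factors[level + 1L]
  if (f == 1) return(mask > 0)
  block_reduce(mask + 0, as.integer(round(f))) > 0.5
}

# metastasis size bands (mm, major axis) used when planting patient labels;
# sampled away from the rule boundaries (0.2 mm, 2 mm) so that recovery is
# not dominated by pixel discretization at the band edge.
label_size_bands <- list(ITC = c(0.08, 0.16), micro = c(0.4, 1.6),
                         macro = c(2.4, 3.6))

#' Default slide spec for synthetic lymph-node patients
#'
#' Uses a coarser physical resolution (8 microns/px) so that the
#' millimetre-scale metastasis size bands fit on a desk-scale raster.
#' @param seed integer seed.
#' @export
patient_slide_spec <- function(seed = 1L) {
  synthetic_slide_spec(width0 = 1024, height0 = 1024, n_tissue_blobs = 2,
                       n_tumor_regions = 1, blob_axis_frac = c(0.32, 0.38),
                       blob_aspect_range = c(0.9, 1),
                       mpp0 = 8, stain_jitter = 0.2, seed = seed)
}

#' Generate a synthetic patient: one slide per lymph node
#'
#' Each slide is planted with a tumor whose largest region's physical
#' major-axis length lies inside the size band of its planned metastasis
#' label (negative slides carry no tumor), so the labels are recoverable
#' by the rule-based size classifier.
#'
#' @param label_plan character vector of per-slide labels drawn from
#'   `negative`, `ITC`, `micro`, `macro`.
#' @param seed integer seed.
#' @param base_spec template [synthetic_slide_spec] for every slide;
#'   tumor counts/sizes are overridden per label.
#' @return list with `slides` (list of `synthetic_slide`), `labels`, and a
#'   `manifest` data.frame (slide_id, label).
#' @export
generate_patient <- function(label_plan, seed = 1L,
                             base_spec = patient_slide_spec()) {
  stopifnot(all(label_plan %in% c("negative", "ITC", "micro", "macro")),
            length(label_plan) >= 1)
  sizes_mm <- with_seed(seed, vapply(label_plan, function(lab) {
    if (lab == "negative") 0 else {
      band <- label_size_bands[[lab]]
      runif(1, band[1], band[2])
    }
  }, 0))
  slides <- vector("list", length(label_plan))
  for (i in seq_along(label_plan)) {
    sp <- base_spec
    sp$seed <- as.integer(seed * 1000L + i) %% .Machine$integer.max
    if (label_plan[i] == "negative") {
      sp$n_tumor_regions <- 0L
    } else {
      px <- sizes_mm[i] * 1000 / sp$mpp0
      sp$n_tumor_regions <- 1L
      sp$tumor_size_range <- c(px, px)
    }
    slides[[i]] <- generate_slide(sp)
  }
  manifest <- data.frame(slide_id = sprintf("slide_%02d", seq_along(label_plan)),
                         label = label_plan, stringsAsFactors = FALSE)
  list(slides = slides, labels = label_plan, manifest = manifest)
}

#' Write a synthetic slide (pyramid, masks, spec) to a directory
#'
#' The pyramid goes to `pyramid/` as per-level PNGs with a JSON sidecar;
#' masks are written as 8-bit {0, 255} PNGs at level 0.
#'
#' @param slide a `synthetic_slide`.
#' @param path output directory.
#' @export
write_slide <- function(slide, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_pyramid(slide$image, file.path(path, "pyramid"))
  png::writePNG(slide$tissue_mask + 0, file.path(path, "tissue_mask.png"))
  png::writePNG(slide$tumor_mask + 0, file.path(path, "tumor_mask.png"))
  png::writePNG(slide$whole_tumor_mask + 0, file.path(path, "whole_tumor_mask.png"))
  jsonlite::write_json(unclass(slide$spec), file.path(path, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
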