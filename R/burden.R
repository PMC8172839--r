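#' Post-process a viable-tumour probability heatmap
#'
#' Binarizes the heatmap and applies the morphological cleanup of the
#' burden algorithm: connected objects smaller than `min_object_px` are
#' removed as false positives and enclosed holes smaller than
#' `max_hole_px` are filled.
#'
#' @param heatmap a `stitched_heatmap` or probability matrix.
#' @param threshold binarization probability in (0, 1).
#' @param min_object_px minimum object size kept, in pixels.
#' @param max_hole_px maximum hole size filled, in pixels.
#' @return logical matrix.
#' @export
postprocess_viable <- function(heatmap, threshold = 0.5, min_object_px = 0L,
                               max_hole_px = 0L) {
  stopifnot(threshold > 0, threshold < 1)
  prob <- if (inherits(heatmap, "stitched_heatmap")) heatmap$prob else heatmap
  m <- prob > threshold
  if (min_object_px > 0 && any(m)) {
    lab <- label_mask(m)
    sizes <- tabulate(lab[lab > 0], max(lab))
    m <- m & matrix(sizes[pmax(lab, 1)] >= min_object_px & lab > 0, nrow(m))
  }
  if (max_hole_px > 0 && any(m)) {
    # holes: background components not touching the border
    bg <- label_mask(!m)
    if (max(bg) > 0) {
      border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
      sizes <- tabulate(bg[bg > 0], max(bg))
      fill <- setdiff(which(sizes < max_hole_px), border_labs)
      if (length(fill)) m <- m | matrix(bg %in% fill, nrow(m))
    }
  }
  m
}

#' Approximate the whole-tumour region
#'
#' The whole tumour (viable tumour plus necrosis and capsule) is
#' approximated as the smallest convex hull containing the entire viable
#' tumour region — one global hull, since each tissue sample carries a
#' single whole-tumour region — intersected with the tissue mask.
#'
#' @param viable logical viable-tumour matrix.
#' @param tissue a `tissue_mask` or binary matrix aligned with `viable`.
#' @return logical whole-tumour matrix (empty when `viable` is empty).
#' @export
estimate_whole_tumor <- function(viable, tissue) {
  tgrid <- if (inherits(tissue, "tissue_mask")) tissue$grid else tissue
  if (!all(dim(viable) == dim(tgrid)))
    stop("viable mask and tissue mask are not aligned")
  if (!any(viable)) return(matrix(FALSE, nrow(viable), ncol(viable)))
  idx <- which(viable)
  h <- nrow(viable)
  xy <- cbind(((idx - 1) %/% h) + 1L, ((idx - 1) %% h) + 1L)
  rasterize_convex_hull(xy, dim(viable)) & (tgrid > 0)
}

#' Viable-tumour burden
#'
#' Burden is the ratio of viable-tumour area to whole-tumour area
#' (0 when the whole-tumour region is empty). The viable mask is
#' intersected with the whole mask first so `viable` is always a subset
#' of `whole`.
#'
#' @param viable,whole aligned logical matrices.
#' @return a `burden_result`: list with `viable_area`, `whole_area`,
#'   `burden` and both masks.
#' @export
compute_burden <- function(viable, whole) {
  stopifnot(all(dim(viable) == dim(whole)))
  viable <- viable & whole
  va <- sum(viable); wa <- sum(whole)
  structure(list(viable_area = va, whole_area = wa,
                 burden = if (wa > 0) va / wa else 0,
                 viable_mask = viable, whole_mask = whole),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("burden_result: viable %d px / whole %d px = %.4f\n",
              x$viable_area, x$whole_area, x$burden))
  invisible(x)
}

#' Full viable-tumour-burden estimation from a heatmap
#'
#' Composes the burden algorithm: threshold and morphologically clean the
#' viable-tumour prediction, approximate the whole tumour as the convex
#' hull of the viable region clipped to tissue, and report the area
#' ratio. Default object/hole sizes scale with the tissue area (0.05%
#' and 0.01% respectively).
#'
#' @inheritParams postprocess_viable
#' @param tissue a `tissue_mask` or binary matrix aligned with the
#'   heatmap.
#' @param min_object_px,max_hole_px morphology sizes; `NULL` uses the
#'   tissue-area-scaled defaults.
#' @return a `burden_result`.
#' @export
estimate_tumor_burden <- function(heatmap, tissue, threshold = 0.5,
                                  min_object_px = NULL, max_hole_px = NULL) {
  tgrid <- if (inherits(tissue, "tissue_mask")) tissue$grid else tissue
  ta <- sum(tgrid > 0)
  if (is.null(min_object_px)) min_object_px <- ceiling(0.0005 * ta)
  if (is.null(max_hole_px)) max_hole_px <- ceiling(0.0001 * ta)
  viable <- postprocess_viable(heatmap, threshold, min_object_px, max_hole_px)
  whole <- estimate_whole_tumor(viable, tgrid)
  compute_burden(viable, whole)
}
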