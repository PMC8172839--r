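#' Test-time-augmentation transform set
#'
#' The invertible transforms used for aleatoric uncertainty estimation:
#' identity, the three right-angle rotations, and the vertical and
#' horizontal flips. Every member has an exact inverse on the pixel grid.
#'
#' @param transforms subset of `c("identity", "rot90", "rot180",
#'   "rot270", "hflip", "vflip")`.
#' @export
tta_set <- function(transforms = c("identity", "rot90", "rot180", "rot270",
                                   "hflip", "vflip")) {
  known <- c("identity", "rot90", "rot180", "rot270", "hflip", "vflip")
  bad <- setdiff(transforms, known)
  if (length(bad)) stop("non-invertible/unknown transforms: ",
                        paste(bad, collapse = ", "))
  structure(transforms, class = "tta_set")
}

apply_tta <- function(m, t) {
  switch(t,
         identity = m,
         rot90 = if (length(dim(m)) == 3) apply_plane(m, rot90_cw) else rot90_cw(m),
         rot180 = if (length(dim(m)) == 3) apply_plane(m, function(x) rot90_cw(x, 2)) else rot90_cw(m, 2),
         rot270 = if (length(dim(m)) == 3) apply_plane(m, function(x) rot90_cw(x, 3)) else rot90_cw(m, 3),
         hflip = if (length(dim(m)) == 3) apply_plane(m, function(x) x[, ncol(x):1]) else m[, ncol(m):1],
         vflip = if (length(dim(m)) == 3) apply_plane(m, function(x) x[nrow(x):1, ]) else m[nrow(m):1, ],
         stop("unknown transform: ", t))
}

invert_tta <- function(m, t) {
  switch(t,
         rot90 = apply_tta(m, "rot270"),
         rot270 = apply_tta(m, "rot90"),
         apply_tta(m, t))    # identity, rot180, flips are involutions
}

pixelwise_population_variance <- function(maps) {
  k <- length(maps)
  mu <- Reduce(`+`, maps) / k
  Reduce(`+`, lapply(maps, function(m) (m - mu)^2)) / k
}

#' Aleatoric uncertainty of a patch via test-time augmentation
#'
#' Predicts on every transformed copy of the patch, maps each output back
#' through the inverse transform, and returns the per-pixel population
#' variance across the aligned maps — the TTA estimate of data-driven
#' uncertainty for one model.
#'
#' @param model a predictor.
#' @param patch RGB array.
#' @param tta a [tta_set] with at least 2 transforms.
#' @param ... context passed to [predict_patch].
#' @return matrix of per-pixel variances (kind "aleatoric").
#' @export
aleatoric_patch <- function(model, patch, tta = tta_set(), ...) {
  if (length(tta) < 2) stop("TTA set must contain at least 2 transforms")
  maps <- lapply(tta, function(t) {
    invert_tta(predict_patch(model, apply_tta(patch, t), tta_transform = t, ...), t)
  })
  v <- pixelwise_population_variance(maps)
  structure(list(grid = v, kind = "aleatoric"), class = "uncertainty_map")
}

#' Epistemic uncertainty of a patch across ensemble members
#'
#' Per-pixel population variance of the member predictions: the spread
#' attributable to model/parameter diversity.
#'
#' @param models list of at least 2 predictors.
#' @inheritParams aleatoric_patch
#' @export
epistemic_patch <- function(models, patch, ...) {
  if (length(models) < 2) stop("epistemic uncertainty needs at least 2 models")
  maps <- lapply(models, predict_patch, patch = patch, ...)
  v <- pixelwise_population_variance(maps)
  structure(list(grid = v, kind = "epistemic"), class = "uncertainty_map")
}

#' Slide-wide uncertainty map
#'
#' Runs the same tissue-mask / sampling-grid / stitching machinery as
#' [run_slide_inference], but stitches per-patch variance maps (averaged
#' at overlaps). Aleatoric maps are computed per model and averaged
#' across the ensemble by default.
#'
#' @inheritParams run_slide_inference
#' @param kind "aleatoric" or "epistemic".
#' @param tta a [tta_set] (aleatoric only).
#' @param per_member return a list of per-member maps instead of the
#'   ensemble mean (aleatoric only).
#' @return list with `uncertainty` (a `stitched_heatmap` whose values are
#'   variances), `tissue`, `kind`.
#' @export
run_slide_uncertainty <- function(img, models, kind = c("aleatoric", "epistemic"),
                                  patch_size = 1024L, stride = 512L,
                                  params = mask_params(), mask_level = NULL,
                                  out_level = NULL, tta = tta_set(),
                                  tissue = NULL, per_member = FALSE) {
  kind <- match.arg(kind)
  if (is.null(tissue)) tissue <- tissue_mask_for_slide(img, params, mask_level)
  if (is.null(out_level)) out_level <- tissue$level
  grid <- build_inference_grid(img, tissue, patch_size, stride)
  one_map <- function(model_or_models, i) {
    ctr <- level_point(grid$centers$x[i], grid$centers$y[i], 0L)
    patch <- read_region(img, ctr, patch_size, level = 0L)
    if (kind == "aleatoric")
      aleatoric_patch(model_or_models, patch, tta, center = ctr, img = img)$grid
    else
      epistemic_patch(model_or_models, patch, center = ctr, img = img)$grid
  }
  stitch_kind <- function(maps) stitch_heatmap(grid, maps, img$width0, img$height0,
                                               out_level = out_level,
                                               factor = infer_factor_step(img))
  if (kind == "epistemic") {
    um <- stitch_kind(lapply(seq_len(nrow(grid$centers)), function(i) one_map(models, i)))
    um$kind <- kind
    return(list(uncertainty = um, tissue = tissue, kind = kind))
  }
  member_maps <- lapply(models, function(mdl)
    lapply(seq_len(nrow(grid$centers)), function(i) one_map(mdl, i)))
  if (per_member) {
    ums <- lapply(member_maps, stitch_kind)
    for (u in seq_along(ums)) ums[[u]]$kind <- kind
    return(list(uncertainty = ums, tissue = tissue, kind = kind))
  }
  avg <- lapply(seq_len(nrow(grid$centers)), function(i) {
    Reduce(`+`, lapply(member_maps, `[[`, i)) / length(models)
  })
  um <- stitch_kind(avg)
  um$kind <- kind
  list(uncertainty = um, tissue = tissue, kind = kind)
}
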