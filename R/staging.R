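#' Ordinal metastasis categories
#'
#' Lymph-node lesion categories in increasing order of severity:
#' negative < ITC < micro < macro.
#' @export
metastasis_levels <- c("negative", "ITC", "micro", "macro")

#' Classify a metastasis by physical size (and optional cell count)
#'
#' Size bands for the largest lesion's major-axis length:
#' 0 = negative; up to 0.2 mm (or fewer than 200 cells) = isolated tumour
#' cells (ITC); above 0.2 mm up to 2 mm = micro-metastasis; above 2 mm =
#' macro-metastasis.
#'
#' @param major_axis_mm largest region's major-axis length in mm (>= 0).
#' @param cell_count optional tumour cell count; `NA` when unknown.
#' @return one of [metastasis_levels].
#' @export
metastasis_type_from_size <- function(major_axis_mm, cell_count = NA_integer_) {
  if (is.na(major_axis_mm) || major_axis_mm < 0)
    stop("major_axis_mm must be a non-negative number")
  if (major_axis_mm == 0) return("negative")
  if (major_axis_mm <= 0.2 || (!is.na(cell_count) && cell_count < 200)) return("ITC")
  if (major_axis_mm <= 2) return("micro")
  "macro"
}

#' Patient pN stage from per-node metastasis labels
#'
#' Aggregates the per-slide (per lymph node) labels into the pathologic
#' pN stage: no findings at all = pN0; only ITCs = pN0(i+);
#' micro-metastases but no macro = pN1mi; at least one macro-metastasis
#' with 1-3 involved nodes = pN1, with 4 or more = pN2. ITC-only nodes do
#' not count toward the pN1/pN2 node tally (consistent with pN0(i+)
#' existing as its own stage); patients with more than 9 involved nodes
#' are clamped to pN2.
#'
#' @param slide_labels non-empty character vector of per-node labels.
#' @return one of "pN0", "pN0(i+)", "pN1mi", "pN1", "pN2".
#' @export
assign_pn_stage <- function(slide_labels) {
  if (length(slide_labels) == 0) stop("at least one slide label is required")
  stopifnot(all(slide_labels %in% metastasis_levels))
  if (all(slide_labels == "negative")) return("pN0")
  if (all(slide_labels %in% c("negative", "ITC"))) return("pN0(i+)")
  if (!any(slide_labels == "macro")) return("pN1mi")
  n_nodes <- sum(slide_labels %in% c("micro", "macro"))
  if (n_nodes <= 3) "pN1" else "pN2"
}

#' Region properties of a labeled binary image
#'
#' Per 8-connected region: pixel area, crack perimeter (count of exposed
#' pixel edges), eccentricity and major-axis length from the second-order
#' central moments, extent (area over bounding-box area), solidity (area
#' over rasterized convex-hull area) and mean intensity under an optional
#' reference image.
#'
#' @param lab integer label matrix (0 = background), e.g. from
#'   [label_mask].
#' @param intensity optional numeric matrix aligned with `lab`.
#' @return data.frame with one row per region.
#' @export
region_properties <- function(lab, intensity = NULL) {
  nreg <- max(lab)
  if (nreg == 0)
    return(data.frame(label = integer(), area = numeric(), perimeter = numeric(),
                      eccentricity = numeric(), extent = numeric(),
                      solidity = numeric(), major_axis = numeric(),
                      mean_intensity = numeric()))
  idx <- which(lab > 0)
  lv <- lab[idx]
  h <- nrow(lab)
  px <- ((idx - 1) %/% h) + 1L     # x = column
  py <- ((idx - 1) %% h) + 1L      # y = row
  area <- as.numeric(tabulate(lv, nreg))

  # crack perimeter: 4*area - 2*(same-label 4-adjacencies)
  same_h <- lab[, -1] == lab[, -ncol(lab)] & lab[, -1] > 0
  adj_h <- tabulate(lab[, -1][same_h], nreg)
  same_v <- lab[-1, ] == lab[-nrow(lab), ] & lab[-1, ] > 0
  adj_v <- tabulate(lab[-1, ][same_v], nreg)
  perimeter <- 4 * area - 2 * (adj_h + adj_v)

  sums <- rowsum(cbind(px, py, px^2, py^2, px * py), lv)
  mx <- sums[, 1] / area; my <- sums[, 2] / area
  mu20 <- sums[, 3] / area - mx^2
  mu02 <- sums[, 4] / area - my^2
  mu11 <- sums[, 5] / area - mx * my
  common <- sqrt(pmax(((mu20 - mu02) / 2)^2 + mu11^2, 0))
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- pmax((mu20 + mu02) / 2 - common, 0)
  major_axis <- 4 * sqrt(pmax(l1, 0))
  eccentricity <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / pmax(l1, 1e-12), 0)), 0)

  xmin <- tapply(px, lv, min); xmax <- tapply(px, lv, max)
  ymin <- tapply(py, lv, min); ymax <- tapply(py, lv, max)
  extent <- area / ((xmax - xmin + 1) * (ymax - ymin + 1))

  solidity <- vapply(seq_len(nreg), function(r) {
    sel <- lv == r
    lx <- px[sel] - xmin[r] + 1L; ly <- py[sel] - ymin[r] + 1L
    hull <- rasterize_convex_hull(cbind(lx, ly),
                                  c(ymax[r] - ymin[r] + 1L, xmax[r] - xmin[r] + 1L))
    area[r] / max(sum(hull), area[r])
  }, 0)

  mean_intensity <- if (is.null(intensity)) rep(NA_real_, nreg)
    else as.numeric(tapply(intensity[idx], lv, mean))

  data.frame(label = seq_len(nreg), area = area, perimeter = perimeter,
             eccentricity = as.numeric(eccentricity),
             extent = as.numeric(extent), solidity = solidity,
             major_axis = major_axis, mean_intensity = mean_intensity)
}

#' 8-connected component labeling of a binary mask
#' @param mask logical/0-1 matrix.
#' @return integer label matrix (0 = background).
#' @export
label_mask <- function(mask) label_components8(mask > 0)

feature_schema <- local({
  props <- c("area", "perimeter", "eccentricity", "extent", "solidity")
  stats <- c("maximum", "mean", "variance", "skewness", "kurtosis")
  rows <- rbind(
    data.frame(name = "major_axis_largest_p090", threshold = 0.9, statistic = "value"),
    data.frame(name = "major_axis_largest_p050", threshold = 0.5, statistic = "value"),
    data.frame(name = "area_largest_p050", threshold = 0.5, statistic = "value"),
    data.frame(name = "tumor_tissue_ratio_p090", threshold = 0.9, statistic = "value"),
    data.frame(name = "nonzero_count_p090", threshold = 0.9, statistic = "value"),
    do.call(rbind, lapply(props, function(p)
      data.frame(name = paste0(p, "_", stats, "_p090"), threshold = 0.9,
                 statistic = stats))),
    data.frame(name = "mean_region_mean_prob_p090", threshold = 0.9, statistic = "value"),
    data.frame(name = "n_regions_p090", threshold = 0.9, statistic = "value"))
  rownames(rows) <- NULL
  rows
})

#' The 32-feature schema used for metastasis-type classification
#' @return data.frame with columns name, threshold, statistic.
#' @export
slide_feature_schema <- function() feature_schema

#' Extract the 32-entry slide feature vector from a tumour heatmap
#'
#' The heatmap is binarized at probabilities 0.5 and 0.9; 8-connected
#' regions and their geometric/morphological properties are measured, and
#' the fixed 32-feature vector is assembled: the largest region's major
#' axis at both thresholds, the largest region's area at 0.5, the
#' tumour/tissue area ratio, the count of supra-threshold pixels, the
#' {maximum, mean, variance, skewness, kurtosis} of the per-region area,
#' perimeter, eccentricity, extent and solidity, the mean of the regions'
#' mean confidence probability, and the number of connected regions (the
#' last 28 all at threshold 0.9). Lengths are in pixels at the heatmap
#' level; the `mpp` attribute carries the microns-per-pixel so size rules
#' can convert to mm downstream. An empty heatmap yields the all-zero
#' vector; with fewer than two regions the dispersion statistics are 0.
#'
#' @param heatmap a `stitched_heatmap` or a probability matrix.
#' @param tissue a `tissue_mask` (or binary matrix) aligned with the
#'   heatmap.
#' @param mpp_at_level microns per pixel at the heatmap level.
#' @return named numeric vector of length 32 with attributes `schema` and
#'   `mpp`.
#' @export
extract_slide_features <- function(heatmap, tissue, mpp_at_level = NA_real_) {
  prob <- if (inherits(heatmap, "stitched_heatmap")) heatmap$prob else heatmap
  tgrid <- if (inherits(tissue, "tissue_mask")) tissue$grid else tissue
  if (!all(dim(prob) == dim(tgrid)))
    stop("heatmap and tissue mask are not aligned")
  lab09 <- label_mask(prob > 0.9)
  lab05 <- label_mask(prob > 0.5)
  rp09 <- region_properties(lab09, prob)
  rp05 <- region_properties(lab05, prob)
  largest <- function(rp, col) if (nrow(rp) == 0) 0 else rp[[col]][which.max(rp$area)]
  stat_block <- function(v) {
    if (length(v) == 0) return(c(0, 0, 0, 0, 0))
    c(max(v), mean(v), pop_var(v), pop_skew(v), pop_kurt(v))
  }
  tissue_area <- sum(tgrid > 0)
  fv <- c(largest(rp09, "major_axis"),
          largest(rp05, "major_axis"),
          largest(rp05, "area"),
          if (tissue_area > 0) sum(prob > 0.9) / tissue_area else 0,
          sum(prob > 0.9),
          unlist(lapply(c("area", "perimeter", "eccentricity", "extent", "solidity"),
                        function(col) stat_block(rp09[[col]]))),
          if (nrow(rp09) > 0) mean(rp09$mean_intensity) else 0,
          nrow(rp09))
  names(fv) <- feature_schema$name
  attr(fv, "schema") <- feature_schema
  attr(fv, "mpp") <- mpp_at_level
  fv
}

#' Rule-based metastasis typing of a heatmap
#'
#' Thresholds the heatmap, finds the largest 8-connected region, converts
#' its major-axis length to millimetres and applies the size rule of
#' [metastasis_type_from_size].
#'
#' @inheritParams extract_slide_features
#' @param threshold binarization probability.
#' @param min_region_px regions smaller than this are ignored (noise).
#' @export
heatmap_metastasis_type <- function(heatmap, mpp_at_level, threshold = 0.5,
                                    min_region_px = 0L) {
  prob <- if (inherits(heatmap, "stitched_heatmap")) heatmap$prob else heatmap
  rp <- region_properties(label_mask(prob > threshold))
  rp <- rp[rp$area >= min_region_px, , drop = FALSE]
  if (nrow(rp) == 0) return("negative")
  mm <- rp$major_axis[which.max(rp$area)] * mpp_at_level / 1000
  metastasis_type_from_size(mm)
}

#' Balance a training set with SMOTE oversampling plus Tomek-link removal
#'
#' Minority classes are oversampled to parity by SMOTE (synthetic points
#' interpolated between a minority sample and one of its k nearest
#' same-class neighbours), then Tomek links — mutual nearest-neighbour
#' pairs from opposite classes — are removed (both ends), cleaning the
#' class boundary. Deterministic for a fixed seed.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y class labels.
#' @param seed integer seed.
#' @param k SMOTE neighbourhood size (capped at class size - 1).
#' @return list(x, y) balanced.
#' @export
balance_training_set <- function(x, y, seed = 1L, k = 5L) {
  x <- as.matrix(x); y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2) stop("need at least 2 classes to balance")
  n_max <- max(tab)
  with_seed(seed, {
    for (cl in names(tab)) {
      n_c <- tab[[cl]]
      if (n_c == n_max) next
      if (n_c < 2)
        stop(sprintf("class '%s' has a single sample; SMOTE needs neighbours", cl))
      xi <- x[y == cl, , drop = FALSE]
      d <- as.matrix(dist(xi)); diag(d) <- Inf
      kk <- min(k, n_c - 1L)
      need <- n_max - n_c
      base <- sample(n_c, need, replace = TRUE)
      syn <- t(vapply(base, function(i) {
        nb <- order(d[i, ])[sample(kk, 1)]
        u <- runif(1)
        xi[i, ] + u * (xi[nb, ] - xi[i, ])
      }, numeric(ncol(x))))
      x <- rbind(x, syn)
      y <- c(y, rep(cl, need))
    }
    # Tomek links on the balanced set
    d <- as.matrix(dist(x)); diag(d) <- Inf
    nn <- apply(d, 1, which.min)
    drop <- logical(length(y))
    for (i in seq_along(y)) {
      j <- nn[i]
      if (nn[j] == i && y[i] != y[j]) drop[i] <- drop[j] <- TRUE
    }
    list(x = x[!drop, , drop = FALSE], y = y[!drop])
  })
}

#' Train an ensemble of Random Forest metastasis-type classifiers
#'
#' Members are trained on distinct data subsets and balancing variants:
#' two stratified subsamples crossed with {raw, SMOTE+Tomek-balanced}
#' training data (four members by default). Prediction is by majority
#' vote with ties broken toward the higher metastasis category.
#'
#' @param x feature matrix (rows = slides, e.g. stacked
#'   [extract_slide_features] vectors).
#' @param y metastasis labels (subset of [metastasis_levels]).
#' @param n_members number of ensemble members (default 4).
#' @param seed integer seed.
#' @param ntree trees per forest.
#' @param subsample_frac stratified fraction per member subset.
#' @return an `rf_ensemble`.
#' @export
train_rf_ensemble <- function(x, y, n_members = 4L, seed = 1L, ntree = 200L,
                              subsample_frac = 0.8) {
  x <- as.matrix(x); y <- as.character(y)
  stopifnot(n_members >= 1)
  if (length(unique(y)) < 2)
    stop("training labels are degenerate: a single class")
  variants <- expand.grid(split = seq_len(ceiling(n_members / 2)),
                          balance = c(FALSE, TRUE))[seq_len(n_members), ]
  members <- lapply(seq_len(n_members), function(m) {
    with_seed(seed * 100L + m, {
      keep <- unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(subsample_frac * length(idx))))
      }))
      xm <- x[keep, , drop = FALSE]; ym <- y[keep]
      if (variants$balance[m] && length(unique(ym)) > 1 && min(table(ym)) >= 2) {
        bal <- balance_training_set(xm, ym, seed = seed * 100L + m)
        xm <- bal$x; ym <- bal$y
      }
      lv <- metastasis_levels[metastasis_levels %in% ym]
      randomForest::randomForest(x = xm, y = factor(ym, levels = lv),
                                 ntree = ntree)
    })
  })
  structure(list(members = members, seed = seed), class = "rf_ensemble")
}

#' @rdname train_rf_ensemble
#' @param ensemble a trained `rf_ensemble`.
#' @param fv a 32-feature vector or a matrix of rows of them.
#' @return predicted label(s) from [metastasis_levels].
#' @export
classify_metastasis <- function(ensemble, fv) {
  if (is.null(dim(fv))) fv <- matrix(fv, 1, dimnames = list(NULL, names(fv)))
  apply(fv, 1, function(row) {
    votes <- vapply(ensemble$members, function(m)
      as.character(predict(m, newdata = matrix(row, 1,
                                               dimnames = list(NULL, colnames(fv))))),
      character(1))
    majority_vote(votes)
  })
}

# majority with ties broken toward the higher ordinal category
majority_vote <- function(votes) {
  tab <- table(factor(votes, levels = metastasis_levels))
  top <- which(tab == max(tab))
  metastasis_levels[max(top)]
}

#' Stage a set of patients from per-slide heatmap feature vectors
#'
#' @param ensemble an `rf_ensemble`.
#' @param features matrix of 32-feature rows.
#' @param patient_ids patient identifier per row.
#' @return data.frame patient, stage, plus per-slide labels as attribute.
#' @export
stage_patients <- function(ensemble, features, patient_ids) {
  labels <- classify_metastasis(ensemble, features)
  stages <- tapply(labels, patient_ids, function(l) assign_pn_stage(as.character(l)))
  data.frame(patient = names(stages), stage = as.character(stages),
             stringsAsFactors = FALSE)
}
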