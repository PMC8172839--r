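test_that("metastasis size bands reproduce the typing rules including boundaries", {
  expect_equal(metastasis_type_from_size(0), "negative")
  expect_equal(metastasis_type_from_size(0.1), "ITC")
  expect_equal(metastasis_type_from_size(0.2), "ITC")      # boundary: <= 0.2 mm
  expect_equal(metastasis_type_from_size(0.1, cell_count = 150), "ITC")
  expect_equal(metastasis_type_from_size(0.5), "micro")
  expect_equal(metastasis_type_from_size(2.0), "micro")    # boundary: <= 2 mm
  expect_equal(metastasis_type_from_size(2.5), "macro")
  expect_equal(metastasis_type_from_size(100), "macro")
  expect_error(metastasis_type_from_size(-1), "non-negative")
})

test_that("pN staging reproduces every rule row", {
  expect_equal(assign_pn_stage(rep("negative", 5)), "pN0")
  expect_equal(assign_pn_stage(c("ITC", rep("negative", 4))), "pN0(i+)")
  expect_equal(assign_pn_stage(c("ITC", "ITC", "ITC")), "pN0(i+)")
  expect_equal(assign_pn_stage(c("micro", rep("negative", 4))), "pN1mi")
  expect_equal(assign_pn_stage(c("micro", "micro", "ITC")), "pN1mi")
  expect_equal(assign_pn_stage(c("macro", "micro", rep("negative", 3))), "pN1")
  expect_equal(assign_pn_stage(c("macro", rep("negative", 4))), "pN1")
  expect_equal(assign_pn_stage(c("macro", "micro", "micro", "micro", "negative")),
               "pN2")
  # ITC-only nodes do not count toward the pN1/pN2 node tally
  expect_equal(assign_pn_stage(c("macro", "ITC", "ITC", "ITC", "ITC")), "pN1")
  expect_error(assign_pn_stage(character(0)), "at least one")
})

test_that("upgrading any slide label never lowers the patient stage", {
  stage_rank <- function(s) match(s, c("pN0", "pN0(i+)", "pN1mi", "pN1", "pN2"))
  set.seed(31)
  for (rep in 1:50) {
    labs <- sample(metastasis_levels, sample(1:5, 1), replace = TRUE)
    i <- sample(length(labs), 1)
    cur <- match(labs[i], metastasis_levels)
    if (cur == 4) next
    up <- labs; up[i] <- metastasis_levels[cur + 1]
    expect_gte(stage_rank(assign_pn_stage(up)), stage_rank(assign_pn_stage(labs)))
  }
})

test_that("the feature vector has the fixed 32-entry schema", {
  sch <- slide_feature_schema()
  expect_equal(nrow(sch), 32)
  expect_equal(sum(sch$threshold == 0.5), 2)     # largest major axis + area at 0.5
  expect_equal(sum(sch$threshold == 0.9), 30)
  stats <- c("maximum", "mean", "variance", "skewness", "kurtosis")
  expect_equal(sum(sch$statistic %in% stats), 25)

  # empty heatmap: all-zero vector of length 32
  fv0 <- extract_slide_features(matrix(0, 32, 32), matrix(1, 32, 32), 1)
  expect_length(fv0, 32)
  expect_true(all(fv0 == 0))

  # any heatmap: still exactly 32 finite entries
  set.seed(2)
  fv <- extract_slide_features(matrix(runif(64 * 64), 64), matrix(1, 64, 64), 1)
  expect_length(fv, 32)
  expect_true(all(is.finite(fv)))
})

test_that("a single 10x10 unit square produces textbook feature values", {
  hm <- matrix(0, 40, 40); hm[11:20, 6:15] <- 1
  tissue <- matrix(1, 40, 40)
  fv <- extract_slide_features(hm, tissue, mpp_at_level = 1)
  expect_equal(unname(fv["area_maximum_p090"]), 100)
  expect_equal(unname(fv["nonzero_count_p090"]), 100)
  expect_equal(unname(fv["n_regions_p090"]), 1)
  expect_equal(unname(fv["tumor_tissue_ratio_p090"]), 100 / 1600)
  expect_equal(unname(fv["perimeter_maximum_p090"]), 40)   # crack perimeter
  expect_equal(unname(fv["extent_maximum_p090"]), 1)
  expect_equal(unname(fv["solidity_maximum_p090"]), 1)
  expect_equal(unname(fv["eccentricity_maximum_p090"]), 0)
  # moment-based major axis of an n-pixel square: 4 * sqrt((n^2 - 1) / 12)
  expect_equal(unname(fv["major_axis_largest_p090"]), 4 * sqrt(99 / 12))
  # single region: dispersion statistics are zero
  expect_equal(unname(fv["area_variance_p090"]), 0)
  expect_equal(unname(fv["area_skewness_p090"]), 0)
  expect_equal(unname(fv["mean_region_mean_prob_p090"]), 1)
})

test_that("region properties agree with a brute-force oracle on random blobs", {
  set.seed(8)
  m <- matrix(FALSE, 48, 48)
  m[5:14, 5:20] <- TRUE                 # rectangle
  m[30:41, 28:39][outer(-5.5:5.5, -5.5:5.5, function(a, b) a^2 + b^2 <= 30)] <- TRUE
  lab <- label_mask(m)
  rp <- region_properties(lab)
  expect_equal(nrow(rp), 2)
  for (r in seq_len(nrow(rp))) {
    pix <- which(lab == r, arr.ind = TRUE)   # (row, col)
    expect_equal(rp$area[r], nrow(pix))
    # brute-force crack perimeter
    per <- 0
    for (i in seq_len(nrow(pix))) {
      for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
        nb <- pix[i, ] + d
        if (nb[1] < 1 || nb[1] > nrow(m) || nb[2] < 1 || nb[2] > ncol(m) ||
            lab[nb[1], nb[2]] != r) per <- per + 1
      }
    }
    expect_equal(rp$perimeter[r], per)
    # brute-force central moments
    x <- pix[, 2]; y <- pix[, 1]
    mu20 <- mean((x - mean(x))^2); mu02 <- mean((y - mean(y))^2)
    mu11 <- mean((x - mean(x)) * (y - mean(y)))
    cm <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    l1 <- (mu20 + mu02) / 2 + cm; l2 <- (mu20 + mu02) / 2 - cm
    expect_equal(rp$major_axis[r], 4 * sqrt(l1), tolerance = 1e-10)
    expect_equal(rp$eccentricity[r], sqrt(1 - l2 / l1), tolerance = 1e-10)
    expect_equal(rp$extent[r],
                 nrow(pix) / ((diff(range(x)) + 1) * (diff(range(y)) + 1)))
  }
})

test_that("8-connected labeling joins diagonal neighbours", {
  m <- matrix(0, 5, 5); m[1, 1] <- 1; m[2, 2] <- 1; m[5, 5] <- 1
  lab <- label_mask(m)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_false(lab[5, 5] == lab[1, 1])
  expect_equal(max(lab), 2)
})

test_that("SMOTE + Tomek balancing behaves per its definition on toy points", {
  set.seed(9)
  xA <- cbind(rnorm(10, 0), rnorm(10, 0))
  xB <- cbind(rnorm(2, 6), rnorm(2, 6))
  x <- rbind(xA, xB); y <- c(rep("A", 10), rep("B", 2))
  bal <- balance_training_set(x, y, seed = 3)
  tab <- table(bal$y)
  expect_lte(max(tab), 10)
  expect_equal(length(unique(bal$y)), 2)
  # synthetic B points lie on segments between the two original B points
  newB <- bal$x[bal$y == "B", , drop = FALSE]
  for (i in seq_len(nrow(newB))) {
    v1 <- xB[2, ] - xB[1, ]; v2 <- newB[i, ] - xB[1, ]
    cross <- v1[1] * v2[2] - v1[2] * v2[1]
    expect_lt(abs(cross), 1e-8)
  }
  # well-separated, already balanced data is untouched
  bal2 <- balance_training_set(rbind(xA, xA + 100), rep(c("A", "B"), each = 10),
                               seed = 1)
  expect_equal(nrow(bal2$x), 20)
  # determinism and the singleton-class error
  b1 <- balance_training_set(x, y, seed = 5)
  b2 <- balance_training_set(x, y, seed = 5)
  expect_identical(b1, b2)
  expect_error(balance_training_set(rbind(xA, xB[1, , drop = FALSE]),
                                    c(rep("A", 10), "B"), seed = 1),
               "'B'")
})

test_that("majority voting breaks ties toward the higher category", {
  expect_equal(wsikit:::majority_vote(c("macro", "macro", "micro", "negative")),
               "macro")
  expect_equal(wsikit:::majority_vote(c("micro", "micro", "macro", "macro")),
               "macro")
  expect_equal(wsikit:::majority_vote(c("negative", "negative", "ITC", "ITC")),
               "ITC")
  expect_equal(wsikit:::majority_vote(c("negative", "ITC", "micro", "macro")),
               "macro")
})

# build separable slide-level features from planted disk heatmaps
synthetic_feature_set <- function(n_per_class = 12, size = 96, mpp = 50, seed = 1) {
  radii_px <- list(negative = NA,
                   ITC = c(1, 2),          # <= 0.2 mm at 50 um/px
                   micro = c(3, 18),       # 0.3 - 1.8 mm
                   macro = c(22, 40))      # > 2.2 mm
  out_x <- NULL; out_y <- c()
  k <- 0
  for (lab in names(radii_px)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      hm <- matrix(0, size, size)
      if (lab != "negative") {
        r <- radii_px[[lab]]
        set.seed(seed * 1000 + k)
        rad <- runif(1, r[1], r[2])
        cx <- size / 2; cy <- size / 2
        xs <- matrix(rep(1:size, each = size), size)
        ys <- matrix(rep(1:size, size), size)
        hm[(xs - cx)^2 + (ys - cy)^2 <= rad^2] <- 1
      }
      fv <- extract_slide_features(hm, matrix(1, size, size), mpp)
      out_x <- rbind(out_x, fv)
      out_y <- c(out_y, lab)
    }
  }
  list(x = out_x, y = out_y)
}

test_that("the RF ensemble learns separable synthetic features", {
  fs <- synthetic_feature_set(n_per_class = 12)
  idx <- rep(seq_len(4), each = 12)
  hold <- unlist(lapply(0:3, function(c4) c4 * 12 + 1:3))   # 3 per class held out
  ens <- train_rf_ensemble(fs$x[-hold, ], fs$y[-hold], seed = 2)
  expect_length(ens$members, 4)
  preds <- classify_metastasis(ens, fs$x[hold, ])
  expect_gte(mean(preds == fs$y[hold]), 0.9)
  # determinism
  ens2 <- train_rf_ensemble(fs$x[-hold, ], fs$y[-hold], seed = 2)
  expect_equal(classify_metastasis(ens2, fs$x[hold, ]), preds)
  expect_error(train_rf_ensemble(fs$x[1:5, ], rep("negative", 5)), "single class")
})

test_that("rule-based typing of heatmap regions honours the mpp conversion", {
  hm <- matrix(0, 64, 64)
  hm[20:40, 20:40] <- 1           # 21 px wide
  # at 100 um/px the diagonal-ish major axis is ~2.4+ mm -> macro
  expect_equal(heatmap_metastasis_type(hm, 100), "macro")
  # at 5 um/px it is ~0.12 mm -> ITC
  expect_equal(heatmap_metastasis_type(hm, 5), "ITC")
  expect_equal(heatmap_metastasis_type(matrix(0, 8, 8), 100), "negative")
})
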