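test_that("ensemble prediction is the pixel-wise posterior mean", {
  patch <- array(0.5, c(8, 8, 3))
  one <- constant_predictor(0.3)
  expect_equal(ensemble_predict(list(one), patch), predict_patch(one, patch))
  two <- list(constant_predictor(0.2), constant_predictor(0.8))
  expect_true(all(ensemble_predict(two, patch) == 0.5))
  three <- list(constant_predictor(0.3), constant_predictor(0.3), constant_predictor(0.3))
  expect_equal(ensemble_predict(three, patch), predict_patch(one, patch))

  bad <- structure(list(), class = c("bad_pred", "predictor"))
  predict_patch.bad_pred <<- function(predictor, patch, ...) matrix(0.5, 2, 2)
  on.exit(rm(predict_patch.bad_pred, envir = globalenv()), add = TRUE)
  expect_error(ensemble_predict(list(one, bad), patch), "different dimensions")
})

test_that("stitching averages overlaps exactly (two half-overlapping patches)", {
  ps <- 8
  g <- patch_grid(data.frame(x = c(4, 8), y = c(4, 4)), ps, 4)
  a <- matrix(0.2, ps, ps); b <- matrix(0.8, ps, ps)
  hm <- stitch_heatmap(g, list(a, b), width0 = 16, height0 = 8)
  expect_true(all(hm$prob[, 1:4] == 0.2))       # only patch a
  expect_true(all(hm$prob[, 5:8] == 0.5))       # overlap strip
  expect_true(all(hm$prob[, 9:12] == 0.8))      # only patch b
  expect_true(all(hm$prob[, 13:16] == 0))       # uncovered
  expect_equal(max(hm$count), 2)
})

test_that("stitching equals a brute-force per-pixel mean on random instances", {
  set.seed(11)
  for (rep in 1:5) {
    W <- sample(60:120, 1); H <- sample(60:120, 1)
    ps <- sample(c(8, 16), 1)
    n <- sample(5:12, 1)
    centers <- data.frame(x = sample(0:(W - 1), n, TRUE),
                          y = sample(0:(H - 1), n, TRUE))
    maps <- replicate(n, matrix(runif(ps * ps), ps), simplify = FALSE)
    hm <- stitch_heatmap(patch_grid(centers, ps, ps), maps, W, H)
    for (k in 1:40) {
      row <- sample(H, 1); col <- sample(W, 1)
      expect_equal(hm$prob[row, col],
                   brute_pixel_mean(centers, ps, maps, row, col),
                   tolerance = 1e-12)
    }
    expect_gte(min(hm$prob), 0); expect_lte(max(hm$prob), 1)
  }
})

test_that("stitching is linear and order-invariant", {
  set.seed(4)
  ps <- 8; W <- H <- 32
  centers <- data.frame(x = c(4, 8, 20, 26), y = c(4, 10, 20, 6))
  g <- patch_grid(centers, ps, 4)
  A <- replicate(4, matrix(runif(64), 8), simplify = FALSE)
  B <- replicate(4, matrix(runif(64), 8), simplify = FALSE)
  mix <- lapply(1:4, function(i) 0.3 * A[[i]] + 0.7 * B[[i]])
  hm_mix <- stitch_heatmap(g, mix, W, H)
  hA <- stitch_heatmap(g, A, W, H); hB <- stitch_heatmap(g, B, W, H)
  expect_equal(hm_mix$prob, 0.3 * hA$prob + 0.7 * hB$prob, tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  hm_perm <- stitch_heatmap(patch_grid(centers[perm, ], ps, 4), A[perm], W, H)
  expect_equal(hm_perm$prob, hA$prob, tolerance = 1e-12)

  expect_error(stitch_heatmap(g, A[1:3], W, H), "does not match")
})

test_that("slide inference with a constant predictor paints tissue only", {
  sl <- test_slide()
  res <- run_slide_inference(sl$image, list(constant_predictor(0.7)),
                             patch_size = 64, stride = 32, out_level = 0)
  covered <- res$heatmap$count > 0
  expect_true(all(abs(res$heatmap$prob[covered] - 0.7) < 1e-12))
  expect_true(all(res$heatmap$prob[!covered] == 0))
  # every covered pixel comes from a tissue-anchored patch
  expect_gt(mean(sl$tissue_mask[covered]), 0.5)
})

test_that("a ground-truth oracle predictor reconstructs the tumor mask", {
  sl <- test_slide()
  res <- run_slide_inference(sl$image, list(oracle_predictor(sl$tumor_mask + 0)),
                             patch_size = 64, stride = 32, out_level = 0)
  expect_gte(mask_iou(res$heatmap$prob > 0.5, sl$tumor_mask), 0.95)
})

test_that("heatmaps can be materialized at a reduced level", {
  sl <- test_slide()
  res0 <- run_slide_inference(sl$image, list(constant_predictor(0.6)),
                              patch_size = 64, stride = 32, out_level = 0)
  res1 <- run_slide_inference(sl$image, list(constant_predictor(0.6)),
                              patch_size = 64, stride = 32, out_level = 1)
  expect_equal(dim(res1$heatmap$prob), dim(res0$heatmap$prob) / 4)
  cov1 <- res1$heatmap$count > 0
  expect_true(all(abs(res1$heatmap$prob[cov1] - 0.6) < 1e-9))
})
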