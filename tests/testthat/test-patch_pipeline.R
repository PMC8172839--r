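test_that("training coordinates are balanced and labels match the footprint rule", {
  sl <- test_slide()
  tm <- tissue_mask_for_slide(sl$image)
  ps <- 64
  coords <- extract_training_coordinates(sl$image, tm, sl$tumor_mask,
                                         n_per_class = 20, patch_size = ps, seed = 3)
  expect_equal(unname(table(coords$label)["tumor"]), 20L)
  expect_equal(unname(table(coords$label)["normal"]), 20L)
  for (i in seq_len(nrow(coords)))
    expect_equal(coords$label[i] == "tumor",
                 brute_footprint_tumor(sl$tumor_mask, coords$x[i], coords$y[i], ps))
  # reproducible per seed; different seed keeps the class counts
  again <- extract_training_coordinates(sl$image, tm, sl$tumor_mask,
                                        n_per_class = 20, patch_size = ps, seed = 3)
  expect_identical(coords, again)
  other <- extract_training_coordinates(sl$image, tm, sl$tumor_mask,
                                        n_per_class = 20, patch_size = ps, seed = 4)
  expect_equal(table(other$label), table(coords$label))
  expect_false(identical(other$x, coords$x))
})

test_that("an empty tumor mask yields normals only, plus a warning", {
  sl <- test_slide()
  tm <- tissue_mask_for_slide(sl$image)
  empty <- matrix(FALSE, nrow(sl$tumor_mask), ncol(sl$tumor_mask))
  expect_warning(
    coords <- extract_training_coordinates(sl$image, tm, empty, n_per_class = 5,
                                           patch_size = 64, seed = 1),
    "fewer eligible")
  expect_equal(sum(coords$label == "normal"), 5)
  expect_equal(sum(coords$label == "tumor"), 0)
  expect_true(attr(coords, "short"))

  blank <- tissue_mask(matrix(0, 8, 8), 0)
  expect_error(extract_training_coordinates(sl$image, blank, empty, 5),
               "empty tissue mask")
})

test_that("coordinate perturbation is a uniform-disk draw with mean 2r/3", {
  expect_equal(perturb_coordinate(50, 60, radius = 0, seed = 1), c(x = 50, y = 60))
  expect_identical(perturb_coordinate(50, 60, radius = 128, seed = 7),
                   perturb_coordinate(50, 60, radius = 128, seed = 7))
  offs <- vapply(1:10000, function(s) {
    p <- perturb_coordinate(1000, 1000, radius = 128, seed = s)
    sqrt(sum((p - c(1000, 1000))^2))
  }, 0)
  expect_lte(max(offs), 128)
  expect_lt(abs(mean(offs) - 2 * 128 / 3) / (2 * 128 / 3), 0.02)
})

test_that("augmentation with everything disabled is the identity", {
  sl <- test_slide()
  patch <- read_region(sl$image, level_point(200, 200), 32)
  mask <- matrix(rbinom(32 * 32, 1, 0.3), 32)
  id <- augmentation_params(flips = FALSE, rot90 = FALSE, gaussian_blur = FALSE,
                            brightness_delta = 0, contrast_delta = 0,
                            hue_delta = 0, saturation_delta = 0)
  out <- augment_patch(patch, mask, id, seed = 2)
  expect_equal(out$patch, patch)
  expect_identical(out$mask, mask)
})

test_that("geometric augmentations transform patch and mask identically", {
  mask <- matrix(0, 16, 16); mask[3:7, 2:12] <- 1
  patch <- array(rep(mask, 3), c(16, 16, 3))    # patch channels mirror the mask
  for (seed in 1:10) {
    out <- augment_patch(patch, mask, augmentation_params(
      brightness_delta = 0, contrast_delta = 0, hue_delta = 0,
      saturation_delta = 0), seed = seed)
    for (ch in 1:3) expect_equal(out$patch[, , ch], out$mask + 0)
  }
})

test_that("hue shifts round-trip through the HSV color model", {
  patch <- array(runif(16 * 16 * 3, 0.2, 0.8), c(16, 16, 3))
  back <- shift_hsv(shift_hsv(patch, hue_shift = 0.25), hue_shift = -0.25)
  expect_lt(max(abs(back - patch)), 1 / 255)
})

test_that("the inference grid matches brute-force lattice enumeration", {
  img <- constant_pyramid(0.5, 512)
  full <- tissue_mask(matrix(1, 512, 512), 0)
  g <- build_inference_grid(img, full, patch_size = 128, stride = 64)
  # brute force: enumerate the lattice and keep tissue-positive centers
  xs <- seq(64, 512 - 64, by = 64)
  expect_equal(nrow(g$centers), length(xs)^2)
  expect_equal(sort(unique(g$centers$x)), xs)
  # row-major: y varies slowest
  expect_true(all(diff(g$centers$y) >= 0))
  # 50% linear overlap at stride = patch/2
  expect_equal(diff(sort(unique(g$centers$x)))[1] / g$patch_size, 0.5)
})

test_that("a single tissue pixel yields exactly one center on that pixel", {
  img <- constant_pyramid(0.5, 64)
  m <- matrix(0, 64, 64); m[21, 31] <- 1     # 0-based (30, 20)
  g <- build_inference_grid(img, tissue_mask(m, 0), patch_size = 1, stride = 1)
  expect_equal(nrow(g$centers), 1)
  expect_equal(c(g$centers$x, g$centers$y), c(30, 20))
})

test_that("grid centers are tissue-positive and spaced by the stride", {
  sl <- test_slide()
  tm <- tissue_mask_for_slide(sl$image)
  g <- build_inference_grid(sl$image, tm, patch_size = 64, stride = 32)
  f <- sl$image$downsample_factors[tm$level + 1]
  for (i in seq_len(nrow(g$centers))) {
    mx <- round(g$centers$x[i] / f); my <- round(g$centers$y[i] / f)
    expect_gt(tm$grid[my + 1, mx + 1], 0)
  }
  xs <- sort(unique(g$centers$x))
  if (length(xs) > 1) expect_true(all(diff(xs) >= g$stride))
  expect_warning(build_inference_grid(sl$image, tissue_mask(matrix(0, 512, 512), 0),
                                      64, 32), "empty tissue mask")
})
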