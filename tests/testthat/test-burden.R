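test_that("post-processing removes small objects and fills small holes", {
  expect_false(any(postprocess_viable(matrix(0, 20, 20))))

  m <- matrix(0, 40, 40)
  m[10:25, 10:25] <- 1                       # large blob
  m[2, 2] <- m[3, 38] <- m[38, 3] <- 1       # 1-px specks
  m[30, 30:32] <- 1                          # 3-px speck
  out <- postprocess_viable(m, min_object_px = 10)
  expect_equal(sum(out), 16 * 16)               # only the blob survives
  expect_true(all(out[10:25, 10:25]))
  expect_false(out[2, 2] || out[30, 30])
  hole <- matrix(0, 30, 30); hole[5:20, 5:20] <- 1
  hole[10:11, 10:12] <- 0                    # 6-px interior hole
  filled <- postprocess_viable(hole, max_hole_px = 10)
  expect_equal(sum(filled), 16 * 16)
  kept <- postprocess_viable(hole, max_hole_px = 5)
  expect_equal(sum(kept), 16 * 16 - 6)       # hole larger than the cap stays
})

test_that("the whole tumor of a convex region is the region itself", {
  m <- matrix(FALSE, 50, 50)
  m[outer(1:50, 1:50, function(y, x) (x - 25)^2 + (y - 25)^2 <= 144)] <- TRUE
  tissue <- matrix(1, 50, 50)
  whole <- estimate_whole_tumor(m, tissue)
  expect_gte(mask_iou(whole, m), 0.99)
  expect_true(all(whole[m]))
  expect_false(any(estimate_whole_tumor(matrix(FALSE, 20, 20), matrix(1, 20, 20))))
})

test_that("the hull of two separated squares matches Pick's-theorem pixel counts", {
  m <- matrix(FALSE, 40, 160)
  m[16:25, 11:20] <- TRUE       # 10x10 square
  m[16:25, 121:130] <- TRUE     # 10x10 square, 100 px gap
  tissue <- matrix(1, 40, 160)
  whole <- estimate_whole_tumor(m, tissue)
  # hull is the 10 x 120 rectangle spanned by the two squares
  expect_equal(sum(whole), 10 * 120)
  expect_true(all(whole[m]))

  # independent oracle on a non-rectangular hull: point-in-polygon (mgcv)
  m2 <- matrix(FALSE, 60, 60)
  m2[10:19, 10:19] <- TRUE
  m2[40:49, 35:44] <- TRUE
  m2[12:16, 45:52] <- TRUE
  whole2 <- estimate_whole_tumor(m2, matrix(1, 60, 60))
  idx <- which(m2); h <- nrow(m2)
  xy <- cbind(((idx - 1) %/% h) + 1, ((idx - 1) %% h) + 1)
  hull <- grDevices::chull(xy)
  bnd <- xy[hull, ]
  px <- rep(1:60, each = 60); py <- rep(1:60, times = 60)
  inside <- mgcv::in.out(rbind(bnd, bnd[1, ]), cbind(px, py))
  oracle <- matrix(FALSE, 60, 60); oracle[cbind(py, px)[inside, ]] <- TRUE
  # implementations may differ exactly on the polygon boundary
  disagree <- sum(xor(whole2, oracle))
  boundary_budget <- 2 * sum(sqrt(rowSums((bnd - bnd[c(2:nrow(bnd), 1), ])^2)))
  expect_lte(disagree, boundary_budget)
  expect_true(all(whole2[oracle & m2]))
})

test_that("the hull is clipped by the tissue mask", {
  m <- matrix(FALSE, 30, 30)
  m[5:10, 5:10] <- TRUE; m[20:25, 20:25] <- TRUE
  tissue <- matrix(0, 30, 30); tissue[1:30, 1:15] <- 1
  whole <- estimate_whole_tumor(m, tissue)
  expect_true(all(which(whole, arr.ind = TRUE)[, 2] <= 15))
})

test_that("burden is the viable/whole area ratio with safe degenerate cases", {
  m <- matrix(FALSE, 20, 20); m[5:10, 5:10] <- TRUE
  br <- compute_burden(m, m)
  expect_equal(br$burden, 1)
  expect_equal(compute_burden(matrix(FALSE, 10, 10), matrix(FALSE, 10, 10))$burden, 0)

  viable <- matrix(FALSE, 40, 160)
  viable[16:25, 11:20] <- TRUE; viable[16:25, 121:130] <- TRUE
  whole <- estimate_whole_tumor(viable, matrix(1, 40, 160))
  br2 <- compute_burden(viable, whole)
  expect_equal(br2$burden, 200 / 1200)
  expect_true(all(br2$viable_mask[br2$viable_mask] %in% TRUE))
  expect_lte(br2$viable_area, br2$whole_area)
})

test_that("burden is stable across grid levels within 2%", {
  sl <- test_slide()
  viable0 <- sl$tumor_mask
  tissue0 <- sl$tissue_mask
  b0 <- compute_burden(viable0, estimate_whole_tumor(viable0, tissue0))$burden
  v1 <- mask_at_level(viable0, sl$image, 1)
  t1 <- mask_at_level(tissue0, sl$image, 1)
  b1 <- compute_burden(v1, estimate_whole_tumor(v1, t1))$burden
  expect_lt(abs(b1 - b0) / b0, 0.02)
})

test_that("burden never decreases when the viable mask grows by dilation", {
  sl <- test_slide()
  viable <- sl$tumor_mask
  tissue <- matrix(1, nrow(viable), ncol(viable))
  b <- compute_burden(viable, estimate_whole_tumor(viable, tissue))$burden
  grown <- wsikit:::from_ebi(EBImage::dilate(wsikit:::as_ebi(viable + 0),
                                             EBImage::makeBrush(5, "disc"))) > 0.5
  b2 <- compute_burden(grown, estimate_whole_tumor(grown, tissue))$burden
  expect_gte(b2 + 1e-9, b)
})
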