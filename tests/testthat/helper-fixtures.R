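# Shared fixtures, generated once per test run.

# default desk-scale slide with two tumor nests
test_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_slide(synthetic_slide_spec(
        width0 = 512, height0 = 512, n_tissue_blobs = 2, n_tumor_regions = 2,
        tumor_size_range = c(50, 90), blob_axis_frac = c(0.18, 0.24), seed = 101))
    cache
  }
})

# uniform-color pyramid (3 levels, factor 4)
constant_pyramid <- function(value = 0.5, size = 64L) {
  build_pyramid(array(value, dim = c(size, size, 3)), n_levels = 3L,
                factor_step = 4L, mpp0 = 1)
}

# brute-force footprint label: does the level-0 patch contain a tumor pixel?
brute_footprint_tumor <- function(tumor_mask0, x, y, patch_size) {
  x0 <- floor(x - patch_size / 2); y0 <- floor(y - patch_size / 2)
  xs <- max(1, x0 + 1):min(ncol(tumor_mask0), x0 + patch_size)
  ys <- max(1, y0 + 1):min(nrow(tumor_mask0), y0 + patch_size)
  any(tumor_mask0[ys, xs] > 0)
}

# brute-force mean of the patch predictions covering one pixel (1-based)
brute_pixel_mean <- function(centers, patch_size, maps, row, col) {
  vals <- c()
  for (i in seq_len(nrow(centers))) {
    x0 <- floor(centers$x[i] - patch_size / 2)
    y0 <- floor(centers$y[i] - patch_size / 2)
    rr <- row - y0; cc <- col - x0        # 1-based position inside the patch
    if (rr >= 1 && rr <= patch_size && cc >= 1 && cc <= patch_size)
      vals <- c(vals, maps[[i]][rr, cc])
  }
  if (length(vals) == 0) 0 else mean(vals)
}
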