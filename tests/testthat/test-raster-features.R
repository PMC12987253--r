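# ROI clipping, masking cascade and spectral features.

test_that("pixel selection matches center-in-buffered-polygon enumeration", {
  # 1 m x 1 m ROI on a 0.05 m grid with a 0.05 m inward buffer:
  # centers in (0.05, 0.95)^2 -> 18 x 18 = 324
  r <- make_raster(nrow = 20L, ncol = 20L, pixel_size = 0.05)
  roi <- square_roi(0, 0, 1, buffer_width = 0.05)
  sel <- clip_and_buffer(r, roi, "Q1")
  expect_equal(nrow(sel), 324L)

  # zero buffer on an ROI exactly tiling the 20 x 20 block -> all 400
  roi0 <- square_roi(0, 0, 1, buffer_width = 0)
  expect_equal(nrow(clip_and_buffer(r, roi0, "Q1")), 400L)

  # ROI fully outside the raster
  far <- square_roi(10, 10, 1)
  expect_error(clip_and_buffer(r, far, "Q1"), "empty ROI")
})

test_that("masking cascade matches hand enumeration on a 3x3 toy ROI", {
  # 7 clean vegetation pixels, 1 shadow (NIR < 0.05 but vegetation-like NDVI),
  # 1 saturated (NIR > 0.95)
  nir <- matrix(c(0.50, 0.51, 0.52, 0.49, 0.02, 0.48, 0.53, 0.97, 0.50), 3L, 3L)
  red <- matrix(0.05, 3L, 3L)
  red[2L, 2L] <- 0.004  # keep the shadow pixel above the NDVI threshold
  r <- make_raster(nrow = 3L, ncol = 3L, pixel_size = 1, NIR = nir, Red = red)
  roi <- square_roi(0, 0, 3, buffer_width = 0)
  masked <- apply_mask_cascade(clip_and_buffer(r, roi, "Q1"), r)
  rep <- masked$report
  expect_equal(rep$n_total, 9L)
  expect_equal(rep$n_nonveg, 0L)
  expect_equal(rep$n_shadow, 1L)
  expect_equal(rep$n_saturated, 1L)
  # inverse-ECDF 1%/99% bounds sit on the extremes of 7 values: none excluded
  expect_equal(sum(unlist(rep$n_quantile_excluded)), 0L)
  expect_equal(rep$n_valid, 7L)
})

test_that("cascade degenerate cases behave as specified", {
  # uniform clean pixels: nothing removed at any stage
  r <- make_raster(nrow = 4L, ncol = 4L, pixel_size = 1)
  roi <- square_roi(0, 0, 4, buffer_width = 0)
  masked <- apply_mask_cascade(clip_and_buffer(r, roi, "Q1"), r)
  expect_equal(masked$report$n_valid, 16L)

  # all bare soil (NDVI = 0.05): empty-ROI error
  soil <- make_raster(nrow = 3L, ncol = 3L, pixel_size = 1,
                      NIR = 0.21, Red = 0.19)
  expect_error(apply_mask_cascade(clip_and_buffer(soil, square_roi(0, 0, 3, 0), "Q1"),
                                  soil),
               "empty ROI")

  # re-running the cascade on its own output is idempotent
  again <- apply_mask_cascade(masked$pixels, r)
  expect_equal(again$report$n_valid, masked$report$n_valid)
  expect_equal(again$pixels$row, masked$pixels$row)
})

test_that("band statistics match a longhand oracle and are permutation-invariant", {
  vals <- matrix(c(0.1, 0.2, 0.3, 0.4), 2L, 2L)
  r <- make_raster(nrow = 2L, ncol = 2L, pixel_size = 1, Blue = vals)
  roi <- square_roi(0, 0, 2, buffer_width = 0)
  sel <- clip_and_buffer(r, roi, "Q1")
  st <- band_statistics(sel, r)
  # longhand: sorted x = (.1 .2 .3 .4); q(p) = x[1+h] + frac interp, h = 3p
  expect_equal(unname(st["Blue_median"]), 0.25)
  expect_equal(unname(st["Blue_p10"]), 0.13)
  expect_equal(unname(st["Blue_p90"]), 0.37)
  expect_equal(unname(st["Blue_mean"]), 0.25)
  expect_equal(unname(st["Blue_std"]), sd(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(unname(st["Blue_min"]), 0.1)
  expect_equal(unname(st["Blue_max"]), 0.4)
  # monotone percentile chain
  chain <- st[paste0("Blue_", c("min", paste0("p", seq(10, 90, 10)), "max"))]
  expect_true(all(diff(chain) >= 0))

  # permuting pixel order changes nothing
  perm <- sel[sample(nrow(sel)), , drop = FALSE]
  attr(perm, "polygon") <- attr(sel, "polygon")
  expect_equal(band_statistics(perm, r), st)

  # constant band: all statistics collapse to the value
  rc <- make_raster(nrow = 2L, ncol = 2L, pixel_size = 1, Blue = 0.4)
  st_c <- band_statistics(clip_and_buffer(rc, roi, "Q1"), rc)
  expect_equal(unname(st_c["Blue_mean"]), 0.4)
  expect_equal(unname(st_c["Blue_p50"]), 0.4)
  expect_equal(unname(st_c["Blue_std"]), 0)

  expect_error(band_statistics(sel[1L, , drop = FALSE], r), "degenerate")
})

test_that("vegetation index means match hand arithmetic", {
  r <- make_raster(nrow = 1L, ncol = 1L, pixel_size = 1, Blue = 0.05,
                   Green = 0.2, Red = 0.1, RedEdge = 0.3, NIR = 0.5)
  sel <- data.frame(row = 1L, col = 1L)
  vi <- vegetation_indices(sel, r, savi_L = 0.5)$means
  expect_equal(unname(vi["NDVI"]), 0.4 / 0.6)
  expect_equal(unname(vi["NDRE"]), 0.2 / 0.8)
  expect_equal(unname(vi["GNDVI"]), 0.3 / 0.7)
  expect_equal(unname(vi["MSR"]), (5 - 1) / (5 + 1))
  expect_equal(unname(vi["EVI"]), 2.5 * 0.4 / (0.5 + 0.6 - 0.375 + 1))
  expect_equal(unname(vi["SAVI"]), 1.5 * 0.4 / (0.5 + 0.1 + 0.5))
})

test_that("vegetation index boundary pixels follow the documented rules", {
  # NIR = Red: NDVI and MSR means are exactly zero
  r_eq <- make_raster(nrow = 2L, ncol = 2L, pixel_size = 1, NIR = 0.3, Red = 0.3)
  sel <- expand.grid(row = 1:2, col = 1:2)
  vi <- vegetation_indices(sel, r_eq)$means
  expect_equal(unname(vi["NDVI"]), 0)
  expect_equal(unname(vi["MSR"]), 0)

  # Red = 0: NDVI = 1; the ratio-form MSR is undefined there and the pixel
  # is dropped from (only) the MSR mean
  r0 <- make_raster(nrow = 1L, ncol = 1L, pixel_size = 1, Red = 0, NIR = 0.5)
  out <- vegetation_indices(data.frame(row = 1L, col = 1L), r0)
  expect_equal(unname(out$means["NDVI"]), 1)
  expect_equal(unname(out$n_dropped["MSR"]), 1L)

  # non-positive EVI denominator: pixel dropped from the EVI mean only
  r_evi <- make_raster(nrow = 1L, ncol = 2L, pixel_size = 1,
                       Blue = matrix(c(0.9, 0.05), 1L), NIR = 0.5, Red = 0.1)
  out2 <- vegetation_indices(expand.grid(row = 1L, col = 1:2), r_evi)
  expect_equal(unname(out2$n_dropped["EVI"]), 1L)
  expect_equal(unname(out2$n_dropped["NDVI"]), 0L)
})

test_that("histogram features per band behave on point masses and report tie-breaks", {
  r <- make_raster(nrow = 2L, ncol = 2L, pixel_size = 1, Blue = 0.3)
  roi <- square_roi(0, 0, 2, buffer_width = 0)
  sel <- clip_and_buffer(r, roi, "Q1")
  hf <- histogram_features(sel, r)
  expect_equal(unname(hf["Blue_peak_frequency"]), 1)
  expect_equal(unname(hf["Blue_distribution_width"]), 0)
  expect_equal(unname(hf["Blue_peak_location"]), 0.3)
})

test_that("quadrat spectral extraction is wired end to end with geometry counts", {
  r <- make_raster(nrow = 20L, ncol = 20L, pixel_size = 0.05)
  roi <- square_roi(0, 0, 1, buffer_width = 0.05)
  out <- spectral_features(r, roi, "Q1")
  expect_equal(unname(out$features["count_total_pixels"]), 324)
  expect_equal(unname(out$features["count_valid_pixels"]), 324)
  expect_equal(unname(out$features["roi_area_m2"]), 0.81, tolerance = 1e-10)
  expect_equal(unname(out$features["NDVI"]), (0.5 - 0.1) / 0.6)
})
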