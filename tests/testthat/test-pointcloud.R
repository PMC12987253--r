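# Ground classification, outlier removal, HAG normalization and canopy
# structure metrics.

grid_cloud <- function(spacing = 0.2, extent = 4, z = 0, intensity = 100) {
  g <- expand.grid(x = seq(0, extent, by = spacing),
                   y = seq(0, extent, by = spacing))
  canopy_cloud(g$x, g$y, rep_len(z, nrow(g)), intensity = intensity)
}

test_that("progressive morphological filter keeps planes and rejects canopy", {
  flat <- grid_cloud(z = 10)
  out <- classify_ground(flat)
  expect_true(all(out$class == "ground"))

  # tilted plane within the slope tolerance stays ground
  tilt <- grid_cloud()
  tilt$z <- 0.1 * tilt$x
  out_t <- classify_ground(tilt, slope_tolerance = 0.15)
  expect_true(all(out_t$class == "ground"))

  # a compact cluster 1.2 m above flat ground is non-ground
  ground <- grid_cloud(z = 0)
  lump <- canopy_cloud(runif(30, 1.8, 2.1), runif(30, 1.8, 2.1), 1.2)
  both <- rbind(ground, lump)
  class(both) <- class(ground)
  out_c <- classify_ground(both)
  expect_true(all(out_c$class[seq_len(nrow(ground))] == "ground"))
  expect_true(all(out_c$class[-seq_len(nrow(ground))] == "unassigned"))

  expect_error(classify_ground(canopy_cloud(rep(1, 5), rep(1, 5), 1:5)),
               "degenerate")
})

test_that("statistical outlier removal flags exactly the isolated point", {
  set.seed(4)
  dense <- canopy_cloud(runif(80), runif(80), runif(80, 0, 0.2))
  far <- canopy_cloud(50, 50, 0)
  cloud <- rbind(dense, far)
  class(cloud) <- class(dense)
  out <- remove_outliers(cloud, k_neighbors = 8L, sd_multiplier = 3)
  expect_equal(which(out$class == "noise"), 81L)

  # brute-force oracle for the kNN mean distances on the same small cloud
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  D <- as.matrix(dist(xyz))
  diag(D) <- Inf
  mk <- apply(D, 1L, function(d) mean(sort(d)[1:8]))
  thr <- mean(mk) + 3 * sd(mk)
  expect_equal(which(mk > thr), c(81L), ignore_attr = TRUE)

  # perfectly regular grid: identical neighbor distances, nothing removed
  reg <- grid_cloud(spacing = 0.5, extent = 3)
  expect_true(all(remove_outliers(reg)$class != "noise"))

  # duplicated points give zero distances without division errors
  dup <- canopy_cloud(rep(1:5, each = 4), rep(1:5, times = 4), 0)
  expect_true(all(remove_outliers(dup, k_neighbors = 3L)$class != "noise"))

  expect_warning(remove_outliers(canopy_cloud(1:3, 1:3, 0), k_neighbors = 8L),
                 "skipped")
})

test_that("HAG normalization subtracts the ground surface and applies the height band", {
  # constant-offset check against an elevated ground plane
  ground <- grid_cloud(z = 5)
  ground$class <- "ground"
  canopy <- canopy_cloud(c(1, 2, 3), c(1, 2, 3), 5.8)
  cloud <- rbind(ground, canopy)
  class(cloud) <- class(ground)
  out <- normalize_hag(cloud)
  expect_equal(out$hag[-seq_len(nrow(ground))], rep(0.8, 3), tolerance = 1e-10)
  expect_error(normalize_hag(canopy), "no ground")

  # boundary enumeration of the closed [0.05, 3.0] band (ground at 0 so the
  # differences are exact in floating point)
  g0 <- grid_cloud(z = 0)
  g0$class <- "ground"
  edge <- canopy_cloud(c(1, 2, 3, 1.5, 2.5), c(1, 2, 3, 2.5, 1.5),
                       c(0.8, 0.04, 0.05, 3.5, 2.99))
  cloud0 <- rbind(g0, edge)
  class(cloud0) <- class(g0)
  out0 <- normalize_hag(cloud0)
  expect_equal(out0$hag[-seq_len(nrow(g0))], c(0.8, 0.04, 0.05, 3.5, 2.99),
               tolerance = 1e-12)
  expect_equal(out0$class[-seq_len(nrow(g0))],
               c("vegetation", "unassigned", "vegetation", "unassigned",
                 "vegetation"))
})

test_that("structural features match direct counting on tiny constructions", {
  roi <- square_roi(0, 0, 4, buffer_width = 0.05)
  # three vegetation points, one per stratum example
  cloud <- canopy_cloud(c(1, 2, 3), c(1, 2, 3), c(0.2, 0.7, 1.2),
                        class = "vegetation", hag = c(0.2, 0.7, 1.2))
  f <- structural_features(cloud, roi, "Q1", min_points = 3L)
  expect_equal(f$strata_0p0_0p5, 1 / 3)
  expect_equal(f$strata_0p5_1p0, 1 / 3)
  expect_equal(f$strata_1p0_1p5, 1 / 3)
  expect_equal(f$strata_1p5_3p0, 0)
  expect_equal(f$coverage_gt_0p3, 2 / 3)
  expect_equal(f$coverage_gt_1p0, 1 / 3)
  expect_equal(f$Hmax, 1.2)

  # constant heights: dispersion metrics all zero
  cloud_c <- canopy_cloud(runif(6, 1, 3), runif(6, 1, 3), 1,
                          class = "vegetation", hag = 1)
  fc <- structural_features(cloud_c, roi, "Q1")
  expect_equal(fc$Hstd, 0)
  expect_equal(fc$Hcv, 0)
  expect_equal(fc$HIQR, 0)
  expect_equal(fc$Hq05, 1)
  expect_equal(fc$Hq95, 1)

  # four points on the corners of a 1 m square: hull area 1
  sq <- canopy_cloud(c(1, 2, 2, 1, 1.5), c(1, 1, 2, 2, 1.5), 0.5,
                     class = "vegetation", hag = 0.5)
  expect_equal(structural_features(sq, roi, "Q1")$hull_area_m2, 1)

  # sparse ROI: flagged record with absent features
  sparse <- structural_features(cloud, roi, "Q1", min_points = 5L)
  expect_true(sparse$sparse)
  expect_true(is.na(sparse$Hmax))
})

test_that("every structural statistic matches a brute-force oracle on a 200-point ROI", {
  set.seed(11)
  n <- 200L
  cloud <- canopy_cloud(runif(n, 0, 2), runif(n, 0, 2), 0,
                        intensity = runif(n, 50, 900),
                        class = "vegetation", hag = runif(n, 0.05, 2.8))
  roi <- square_roi(0, 0, 2, buffer_width = 0.05)
  f <- structural_features(cloud, roi, "Q1")

  poly_side <- 2 - 2 * 0.05
  inside <- cloud$x > 0.05 & cloud$x < 1.95 & cloud$y > 0.05 & cloud$y < 1.95
  h <- cloud$hag[inside]
  it <- cloud$intensity[inside]
  # longhand type-7 quantile
  q7 <- function(x, p) {
    xs <- sort(x); hh <- (length(x) - 1) * p
    lo <- floor(hh)
    xs[lo + 1] + (hh - lo) * (xs[pmin(lo + 2, length(x))] - xs[lo + 1])
  }
  expect_equal(f$Hmax, max(h), tolerance = 1e-10)
  expect_equal(f$Hmean, sum(h) / length(h), tolerance = 1e-10)
  expect_equal(f$Hstd, sqrt(sum((h - mean(h))^2) / (length(h) - 1)), tolerance = 1e-10)
  expect_equal(f$Hcv, f$Hstd / f$Hmean, tolerance = 1e-10)
  for (p in c(0.05, 0.25, 0.75, 0.95)) {
    nm <- sprintf("Hq%02d", round(100 * p))
    expect_equal(f[[nm]], q7(h, p), tolerance = 1e-10)
  }
  expect_equal(f$HIQR, f$Hq75 - f$Hq25, tolerance = 1e-10)
  expect_equal(f$density_vegetation, length(h) / poly_side^2, tolerance = 1e-10)
  expect_equal(f$coverage_gt_0p3, sum(h > 0.3) / length(h), tolerance = 1e-10)
  expect_equal(f$strata_0p5_1p0, sum(h >= 0.5 & h < 1.0) / length(h), tolerance = 1e-10)
  expect_equal(f$IntensityMean, sum(it) / length(it), tolerance = 1e-10)
  expect_equal(f$IntensityStd, sqrt(sum((it - mean(it))^2) / (length(it) - 1)),
               tolerance = 1e-10)
  expect_equal(f$strata_0p0_0p5 + f$strata_0p5_1p0 + f$strata_1p0_1p5 +
                 f$strata_1p5_3p0, 1, tolerance = 1e-12)
  expect_true(f$density_vegetation <= f$density_total)
})

test_that("structural features are invariant to point order and rigid translation", {
  set.seed(12)
  n <- 60L
  cloud <- canopy_cloud(runif(n, 0, 2), runif(n, 0, 2), 0,
                        intensity = runif(n, 100, 500),
                        class = "vegetation", hag = runif(n, 0.1, 2))
  roi <- square_roi(0, 0, 2)
  f1 <- structural_features(cloud, roi, "Q1")

  perm <- cloud[sample(n), , drop = FALSE]
  class(perm) <- class(cloud)
  expect_equal(structural_features(perm, roi, "Q1"), f1)

  shift <- cloud
  shift$x <- shift$x + 10
  shift$y <- shift$y - 3
  roi_s <- square_roi(10, -3, 2)
  f2 <- structural_features(shift, roi_s, "Q1")
  expect_equal(f2, f1, tolerance = 1e-10)
})

test_that("clouds round-trip through CSV", {
  dir <- withr::local_tempdir()
  cloud <- canopy_cloud(1:4, 4:1, c(0, 0.5, 1, 2), intensity = c(10, 20, 30, 40),
                        class = c("ground", "vegetation", "vegetation", "noise"),
                        hag = c(0, 0.5, 1, 2))
  p <- file.path(dir, "cloud.csv")
  write_cloud(cloud, p)
  expect_equal(read_cloud(p), cloud)
})
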