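# Canopy structure metrics per quadrat ROI, computed over HAG-normalized
# vegetation points.

STRUCTURAL_FEATURES <- c(
  "Hmax", "Hmean", "Hstd", "Hcv",
  "Hq05", "Hq10", "Hq25", "Hq50", "Hq75", "Hq90", "Hq95", "HIQR",
  "density_total", "density_vegetation",
  "coverage_gt_0p3", "coverage_gt_1p0",
  "strata_0p0_0p5", "strata_0p5_1p0", "strata_1p0_1p5", "strata_1p5_3p0",
  "IntensityMean", "IntensityStd",
  "Intensity_peak_location", "Intensity_peak_frequency",
  "Intensity_distribution_width",
  "hull_area_m2"
)

#' Canopy structural features of a quadrat
#'
#' Computes the height, density, coverage, vertical-stratification, echo
#' intensity and hull geometry descriptors of the vegetation points falling
#' inside the inward-buffered ROI polygon. Height strata are half-open
#' `[0, 0.5)`, `[0.5, 1.0)`, `[1.0, 1.5)` m with a closed top bin
#' `[1.5, 3.0]`; coverage uses strict `H > 0.3` m and `H > 1.0` m; height
#' percentiles use the linear-interpolation convention shared with the band
#' statistics. Densities are counts per buffered-ROI area: `density_total`
#' over all non-noise points, `density_vegetation` over vegetation points.
#'
#' @param cloud A HAG-normalized `canopy_cloud`.
#' @param rois A `quadrat_rois` table.
#' @param id Quadrat id to extract (one of `rois$id`).
#' @param min_points Minimum vegetation points required (default 5); sparser
#'   ROIs return a flagged record with `NA` features.
#' @return Named list of features plus `n_vegetation` and `sparse` flags.
#' @export
structural_features <- function(cloud, rois, id, min_points = 5L) {
  if (!"hag" %in% names(cloud)) stop("cloud must be HAG-normalized first", call. = FALSE)
  i <- match(as.character(id), rois$id)
  if (is.na(i)) stop("unknown quadrat id: ", id, call. = FALSE)
  poly <- buffer_inward(roi_polygon(rois, id), rois$buffer_width[i])
  area <- polygon_area(poly)

  inside <- point_in_polygon(cloud$x, cloud$y, poly)
  sub <- cloud[inside & cloud$class != "noise", , drop = FALSE]
  veg <- sub[sub$class == "vegetation", , drop = FALSE]

  out <- stats::setNames(as.list(rep(NA_real_, length(STRUCTURAL_FEATURES))),
                         STRUCTURAL_FEATURES)
  out$n_vegetation <- nrow(veg)
  out$sparse <- nrow(veg) < min_points
  if (out$sparse) return(out)

  h <- veg$hag
  q <- pct_linear(h, c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95))
  out$Hmax <- max(h)
  out$Hmean <- mean(h)
  out$Hstd <- stats::sd(h)
  out$Hcv <- if (out$Hmean > 0) out$Hstd / out$Hmean else 0
  out[c("Hq05", "Hq10", "Hq25", "Hq50", "Hq75", "Hq90", "Hq95")] <- as.list(q)
  out$HIQR <- q[5L] - q[3L]
  out$density_total <- nrow(sub) / area
  out$density_vegetation <- nrow(veg) / area
  out$coverage_gt_0p3 <- mean(h > 0.3)
  out$coverage_gt_1p0 <- mean(h > 1.0)
  out$strata_0p0_0p5 <- mean(h < 0.5)
  out$strata_0p5_1p0 <- mean(h >= 0.5 & h < 1.0)
  out$strata_1p0_1p5 <- mean(h >= 1.0 & h < 1.5)
  out$strata_1p5_3p0 <- mean(h >= 1.5)
  out$IntensityMean <- mean(veg$intensity)
  out$IntensityStd <- stats::sd(veg$intensity)
  ih <- histogram_shape(veg$intensity)
  out$Intensity_peak_location <- ih$peak_location
  out$Intensity_peak_frequency <- ih$peak_frequency
  out$Intensity_distribution_width <- ih$distribution_width
  out$hull_area_m2 <- convex_hull_area(veg$x, veg$y)
  out
}
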