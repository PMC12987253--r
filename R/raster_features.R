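# Spectral feature extraction per buffered quadrat ROI: pixel selection,
# masking cascade, band statistics, histogram-shape features, vegetation
# index means and geometric counts.

#' Select the raster pixels of a buffered ROI
#'
#' Applies the inward buffer to the quadrat polygon and returns the pixels
#' whose centers fall inside it (pixel-center test, nodata pixels retained
#' and reported downstream).
#'
#' @param raster A `reflectance_raster`.
#' @param rois A `quadrat_rois` table.
#' @param id Quadrat id.
#' @return A `data.frame` with pixel `row`, `col` indices, carrying the
#'   buffered polygon and the roi id as attributes.
#' @export
clip_and_buffer <- function(raster, rois, id) {
  i <- match(as.character(id), rois$id)
  if (is.na(i)) stop("unknown quadrat id: ", id, call. = FALSE)
  poly <- buffer_inward(roi_polygon(rois, id), rois$buffer_width[i])
  ext <- raster_extent(raster)
  d <- dim(raster$bands[[1L]])
  # restrict the center test to the polygon's bounding box
  cmin <- max(1L, floor((min(poly[, 1L]) - ext["xmin"]) / raster$pixel_size) + 1L)
  cmax <- min(d[2L], ceiling((max(poly[, 1L]) - ext["xmin"]) / raster$pixel_size))
  rmin <- max(1L, floor((ext["ymax"] - max(poly[, 2L])) / raster$pixel_size) + 1L)
  rmax <- min(d[1L], ceiling((ext["ymax"] - min(poly[, 2L])) / raster$pixel_size))
  if (cmin > cmax || rmin > rmax) {
    stop("empty ROI: quadrat ", id, " selects no pixels", call. = FALSE)
  }
  grid <- expand.grid(row = rmin:rmax, col = cmin:cmax)
  ctr <- pixel_centers(raster, grid$row, grid$col)
  keep <- point_in_polygon(ctr[, 1L], ctr[, 2L], poly)
  if (!any(keep)) stop("empty ROI: quadrat ", id, " selects no pixels", call. = FALSE)
  sel <- grid[keep, , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "polygon") <- poly
  attr(sel, "roi_id") <- as.character(id)
  sel
}

# Band values at selected pixels as an n x 5 matrix.
pixel_values <- function(raster, pixels) {
  idx <- cbind(pixels$row, pixels$col)
  v <- vapply(raster$bands, function(b) b[idx], numeric(nrow(pixels)))
  if (nrow(pixels) == 1L) v <- matrix(v, nrow = 1L, dimnames = list(NULL, names(raster$bands)))
  v
}

#' Masking cascade for ROI pixels
#'
#' Sequentially removes (1) non-vegetation pixels with raw
#' `NDVI < ndvi_min`, (2) shadow pixels with `NIR < nir_min`, (3) saturated
#' pixels with any band above `sat_max`, then (4) per band among the
#' survivors, pixels strictly below the 1st or strictly above the 99th
#' percentile (inverse-ECDF percentiles, so small ROIs lose nothing at this
#' stage). Cross-band features use the intersection of the per-band
#' survivors. Nodata pixels are discarded before the cascade.
#'
#' @param pixels Pixel selection from [clip_and_buffer()].
#' @param raster A `reflectance_raster`.
#' @param ndvi_min,nir_min,sat_max,q_low,q_high Cascade thresholds
#'   (defaults 0.20, 0.05, 0.95, 0.01, 0.99).
#' @return List with `pixels` (the valid selection) and `report`
#'   (a `pixel_mask_report`: `n_total`, `n_nodata`, `n_nonveg`, `n_shadow`,
#'   `n_saturated`, `n_quantile_excluded` per band, `n_valid`).
#' @export
apply_mask_cascade <- function(pixels, raster, ndvi_min = 0.20, nir_min = 0.05,
                               sat_max = 0.95, q_low = 0.01, q_high = 0.99) {
  id <- attr(pixels, "roi_id")
  n_total <- nrow(pixels)
  if (n_total == 0L) stop("empty ROI selection", call. = FALSE)
  v <- pixel_values(raster, pixels)
  nodata <- raster$nodata_mask[cbind(pixels$row, pixels$col)] | !stats::complete.cases(v)
  alive <- !nodata

  ndvi <- (v[, "NIR"] - v[, "Red"]) / (v[, "NIR"] + v[, "Red"])
  nonveg <- alive & (!is.finite(ndvi) | ndvi < ndvi_min)
  alive <- alive & !nonveg
  shadow <- alive & v[, "NIR"] < nir_min
  alive <- alive & !shadow
  saturated <- alive & apply(v > sat_max, 1L, any)
  alive <- alive & !saturated

  n_quant <- stats::setNames(integer(ncol(v)), colnames(v))
  if (any(alive)) {
    keep_band <- matrix(TRUE, sum(alive), ncol(v))
    va <- v[alive, , drop = FALSE]
    for (k in seq_len(ncol(v))) {
      lo <- pct_ecdf(va[, k], q_low)
      hi <- pct_ecdf(va[, k], q_high)
      keep_band[, k] <- va[, k] >= lo & va[, k] <= hi
      n_quant[k] <- sum(!keep_band[, k])
    }
    valid_sub <- apply(keep_band, 1L, all)
    alive[alive] <- valid_sub
  }
  if (!any(alive)) {
    stop("empty ROI after masking", if (!is.null(id)) paste0(": quadrat ", id),
         call. = FALSE)
  }
  report <- structure(
    list(n_total = n_total, n_nodata = sum(nodata), n_nonveg = sum(nonveg),
         n_shadow = sum(shadow), n_saturated = sum(saturated),
         n_quantile_excluded = as.list(n_quant), n_valid = sum(alive)),
    class = "pixel_mask_report"
  )
  out <- pixels[alive, , drop = FALSE]
  attr(out, "polygon") <- attr(pixels, "polygon")
  attr(out, "roi_id") <- id
  list(pixels = out, report = report)
}

#' @export
print.pixel_mask_report <- function(x, ...) {
  cat(sprintf(
    "<pixel_mask_report> %d px: %d nodata, %d non-veg, %d shadow, %d saturated -> %d valid\n",
    x$n_total, x$n_nodata, x$n_nonveg, x$n_shadow, x$n_saturated, x$n_valid))
  invisible(x)
}

#' Per-band reflectance statistics
#'
#' Mean, median, sample standard deviation, min, max and the 10th-90th
#' percentiles (steps of 10, linear interpolation) of each band over the
#' valid pixels.
#'
#' @param pixels Valid pixel selection.
#' @param raster A `reflectance_raster`.
#' @return Named numeric vector (`<Band>_mean`, `<Band>_median`,
#'   `<Band>_std`, `<Band>_min`, `<Band>_max`, `<Band>_p10` ... `<Band>_p90`).
#' @export
band_statistics <- function(pixels, raster) {
  if (nrow(pixels) < 2L) {
    stop("degenerate ROI: fewer than 2 valid pixels", call. = FALSE)
  }
  v <- pixel_values(raster, pixels)
  out <- numeric(0)
  for (b in colnames(v)) {
    x <- v[, b]
    p <- pct_linear(x, seq(0.1, 0.9, by = 0.1))
    vals <- c(mean(x), stats::median(x), stats::sd(x), min(x), max(x), p)
    names(vals) <- paste0(b, "_", c("mean", "median", "std", "min", "max",
                                    paste0("p", seq(10, 90, by = 10))))
    out <- c(out, vals)
  }
  out
}

#' Per-band histogram-shape features
#'
#' Fixed-bin histogram features (see [histogram_shape()]) of each band over
#' the valid pixels.
#'
#' @inheritParams band_statistics
#' @param n_bins Number of histogram bins (default 50).
#' @return Named numeric vector (`<Band>_peak_location`,
#'   `<Band>_peak_frequency`, `<Band>_distribution_width`).
#' @export
histogram_features <- function(pixels, raster, n_bins = 50L) {
  if (nrow(pixels) < 2L) {
    stop("degenerate ROI: fewer than 2 valid pixels", call. = FALSE)
  }
  v <- pixel_values(raster, pixels)
  out <- numeric(0)
  for (b in colnames(v)) {
    h <- histogram_shape(v[, b], n_bins = n_bins)
    vals <- c(h$peak_location, h$peak_frequency, h$distribution_width)
    names(vals) <- paste0(b, "_", c("peak_location", "peak_frequency",
                                    "distribution_width"))
    out <- c(out, vals)
  }
  out
}

#' Vegetation index means
#'
#' Per-pixel NDVI, NDRE, GNDVI, MSR, EVI and SAVI, averaged over the valid
#' pixels. Pixels where an index's denominator is non-positive (EVI, SAVI)
#' or undefined (MSR with zero Red) are dropped from that index's mean and
#' counted.
#'
#' @inheritParams band_statistics
#' @param savi_L SAVI soil adjustment factor (default 0.5).
#' @return List with `means` (named numeric vector `NDVI`, `NDRE`, `GNDVI`,
#'   `MSR`, `EVI`, `SAVI`) and `n_dropped` (pixels excluded per index).
#' @export
vegetation_indices <- function(pixels, raster, savi_L = 0.5) {
  if (nrow(pixels) < 1L) stop("no valid pixels", call. = FALSE)
  v <- pixel_values(raster, pixels)
  nir <- v[, "NIR"]; red <- v[, "Red"]; blue <- v[, "Blue"]
  green <- v[, "Green"]; rededge <- v[, "RedEdge"]
  per_pixel <- list(
    NDVI = (nir - red) / (nir + red),
    NDRE = (nir - rededge) / (nir + rededge),
    GNDVI = (nir - green) / (nir + green),
    MSR = (nir / red - 1) / (nir / red + 1),
    EVI = {
      den <- nir + 6 * red - 7.5 * blue + 1
      ifelse(den > 0, 2.5 * (nir - red) / den, NA_real_)
    },
    SAVI = {
      den <- nir + red + savi_L
      ifelse(den > 0, 1.5 * (nir - red) / den, NA_real_)
    }
  )
  means <- vapply(per_pixel, function(x) mean(x[is.finite(x)]), numeric(1))
  dropped <- vapply(per_pixel, function(x) sum(!is.finite(x)), integer(1))
  list(means = means, n_dropped = dropped)
}

#' All spectral features of a quadrat
#'
#' Runs the clip, masking cascade, band statistics, histogram features,
#' vegetation indices and geometric counts for one quadrat.
#'
#' @param raster A `reflectance_raster`.
#' @param rois A `quadrat_rois` table.
#' @param id Quadrat id.
#' @param n_bins Histogram bins (default 50).
#' @param savi_L SAVI soil factor (default 0.5).
#' @param ... Cascade thresholds passed to [apply_mask_cascade()].
#' @return List with `features` (named numeric vector) and `report`
#'   (the `pixel_mask_report`).
#' @export
spectral_features <- function(raster, rois, id, n_bins = 50L, savi_L = 0.5, ...) {
  sel <- clip_and_buffer(raster, rois, id)
  masked <- apply_mask_cascade(sel, raster, ...)
  vi <- vegetation_indices(masked$pixels, raster, savi_L = savi_L)
  feats <- c(
    band_statistics(masked$pixels, raster),
    histogram_features(masked$pixels, raster, n_bins = n_bins),
    vi$means,
    roi_area_m2 = polygon_area(attr(sel, "polygon")),
    count_valid_pixels = masked$report$n_valid,
    count_total_pixels = masked$report$n_total
  )
  list(features = feats, report = masked$report)
}
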