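# Canopy point cloud container, classification and height normalization.
# Points carry x, y, z (m), laser echo intensity, a class label
# (ground / vegetation / noise / unassigned) and, after normalization, a
# height-above-ground (hag) column. Clouds are stored as plain data frames
# and interchanged as CSV.

CLOUD_CLASSES <- c("ground", "vegetation", "noise", "unassigned")

#' Construct a canopy point cloud
#'
#' @param x,y,z Point coordinates (m).
#' @param intensity Laser echo intensity (unitless, `>= 0`).
#' @param class Class labels among `ground`, `vegetation`, `noise`,
#'   `unassigned` (default `unassigned`).
#' @param hag Optional height above ground (m), present only after
#'   [normalize_hag()].
#' @return A `data.frame` of class `canopy_cloud`.
#' @export
canopy_cloud <- function(x, y, z, intensity = 0, class = "unassigned", hag = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  z <- rep_len(as.numeric(z), n)
  class <- rep_len(as.character(class), n)
  if (!all(class %in% CLOUD_CLASSES)) stop("unknown point class label", call. = FALSE)
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   intensity = rep_len(as.numeric(intensity), n),
                   class = class, stringsAsFactors = FALSE)
  if (!is.null(hag)) df$hag <- rep_len(as.numeric(hag), n)
  structure(df, class = c("canopy_cloud", "data.frame"))
}

#' @export
print.canopy_cloud <- function(x, ...) {
  tab <- table(factor(x$class, levels = CLOUD_CLASSES))
  cat(sprintf("<canopy_cloud> %d points (%s)%s\n", nrow(x),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              if ("hag" %in% names(x)) ", HAG-normalized" else ""))
  invisible(x)
}

#' Write and read a point cloud as CSV
#'
#' Columns: `x, y, z, intensity, class[, hag]`.
#'
#' @param cloud A `canopy_cloud`.
#' @param path CSV file path.
#' @return `read_cloud()` returns a `canopy_cloud`; `write_cloud()` returns
#'   `path` invisibly.
#' @export
write_cloud <- function(cloud, path) {
  utils::write.csv(as.data.frame(cloud), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cloud
#' @export
read_cloud <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  canopy_cloud(df$x, df$y, df$z, intensity = df$intensity,
               class = if (is.null(df$class)) "unassigned" else df$class,
               hag = df$hag)
}

# Crop a cloud to a rectangular window (used by the pipeline to process
# quadrat neighborhoods independently).
crop_cloud <- function(cloud, xmin, xmax, ymin, ymax) {
  keep <- cloud$x >= xmin & cloud$x <= xmax & cloud$y >= ymin & cloud$y <= ymax
  cloud[keep, , drop = FALSE]
}

# --- ground classification ---------------------------------------------------

# Morphological opening (erosion then dilation) of a grid surface with a
# square window of half-width `r` cells. NA cells are ignored.
grid_opening <- function(g, r) {
  erode <- function(m) {
    out <- m
    nr <- nrow(m); nc <- ncol(m)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        out[i, j] <- suppressWarnings(
          min(m[max(1L, i - r):min(nr, i + r),
                max(1L, j - r):min(nc, j + r)], na.rm = TRUE))
      }
    }
    out[!is.finite(out)] <- NA_real_
    out
  }
  dilate <- function(m) {
    out <- m
    nr <- nrow(m); nc <- ncol(m)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        out[i, j] <- suppressWarnings(
          max(m[max(1L, i - r):min(nr, i + r),
                max(1L, j - r):min(nc, j + r)], na.rm = TRUE))
      }
    }
    out[!is.finite(out)] <- NA_real_
    out
  }
  dilate(erode(g))
}

#' Classify ground points with a progressive morphological filter
#'
#' Builds a minimum-elevation grid, applies morphological openings with
#' windows of increasing size, and flags a point as non-ground as soon as its
#' elevation exceeds the opened surface by more than the window's elevation
#' threshold. Thresholds grow with window size at `slope_tolerance` so that
#' terrain slopes up to the tolerance survive as ground while compact
#' above-ground objects (canopy) are removed.
#'
#' @param cloud A `canopy_cloud` (noise points are ignored).
#' @param cell_size Grid cell size (m), default 0.25.
#' @param max_window Largest opening window diameter (m), default 2.
#' @param slope_tolerance Terrain slope tolerance (m/m), default 0.15.
#' @param dh0 Initial elevation threshold (m), default 0.05.
#' @param dh_max Threshold cap (m), default 1.
#' @return The cloud with `class` set to `ground` / `unassigned`
#'   (noise labels are preserved).
#' @export
classify_ground <- function(cloud, cell_size = 0.25, max_window = 2,
                            slope_tolerance = 0.15, dh0 = 0.05, dh_max = 1) {
  active <- cloud$class != "noise"
  pts <- cloud[active, , drop = FALSE]
  if (nrow(pts) < 3L) stop("need at least 3 points to classify ground", call. = FALSE)
  if (diff(range(pts$x)) == 0 && diff(range(pts$y)) == 0) {
    stop("degenerate extent: all points coincident in xy", call. = FALSE)
  }
  ci <- pmax(1L, ceiling((pts$x - min(pts$x)) / cell_size))
  ri <- pmax(1L, ceiling((pts$y - min(pts$y)) / cell_size))
  nr <- max(ri); nc <- max(ci)
  surf <- matrix(NA_real_, nr, nc)
  cell <- (ci - 1L) * nr + ri
  mins <- tapply(pts$z, cell, min)
  surf[as.integer(names(mins))] <- mins

  is_ground <- rep(TRUE, nrow(pts))
  radii <- 1L
  while (utils::tail(radii, 1L) * 2L * cell_size < max_window) {
    radii <- c(radii, utils::tail(radii, 1L) * 2L)
  }
  for (r in radii) {
    opened <- grid_opening(surf, r)
    dh <- min(dh0 + slope_tolerance * (2 * r * cell_size), dh_max)
    above <- pts$z - opened[cell]
    is_ground <- is_ground & !is.na(above) & above <= dh
    surf <- opened
  }
  cloud$class[active] <- ifelse(is_ground, "ground", "unassigned")
  cloud
}

# --- statistical outlier removal --------------------------------------------

#' Remove outliers by neighborhood statistics
#'
#' Labels as `noise` every point whose mean distance to its `k_neighbors`
#' nearest neighbors exceeds the cloud-wide mean plus `sd_multiplier`
#' standard deviations of that quantity (3D distances, brute force).
#'
#' @param cloud A `canopy_cloud`.
#' @param k_neighbors Number of neighbors (default 8).
#' @param sd_multiplier Threshold multiplier (default 3).
#' @return The cloud with outliers labeled `noise`. If the cloud has at most
#'   `k_neighbors` points it is returned unchanged with a warning.
#' @export
remove_outliers <- function(cloud, k_neighbors = 8L, sd_multiplier = 3) {
  n <- nrow(cloud)
  if (n <= k_neighbors) {
    warning("fewer points than k_neighbors + 1; outlier filter skipped")
    return(cloud)
  }
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  mean_knn <- numeric(n)
  block <- 2048L
  sq <- rowSums(xyz^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(xyz[idx, , drop = FALSE], xyz)
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    d2[d2 < 0] <- 0
    mean_knn[idx] <- apply(d2, 1L, function(row) {
      mean(sqrt(sort.int(row, partial = k_neighbors)[seq_len(k_neighbors)]))
    })
  }
  thr <- mean(mean_knn) + sd_multiplier * stats::sd(mean_knn)
  cloud$class[mean_knn > thr] <- "noise"
  cloud
}

# --- HAG normalization -------------------------------------------------------

#' Normalize heights above ground and retain vegetation points
#'
#' Interpolates a ground surface from the grid-minimum of classified ground
#' points (bilinear between cell centers, nearest cell beyond the data
#' margin), sets `hag = z - ground`, and labels non-ground, non-noise points
#' with `hag` in `[hag_min, hag_max]` (defaults `[0.05, 3.0]` m, closed
#' bounds) as `vegetation`. Points outside the band stay `unassigned` and are
#' excluded from vegetation features.
#'
#' @param cloud A `canopy_cloud` with ground points classified.
#' @param cell_size Ground grid cell size (m), default 0.25.
#' @param hag_min,hag_max Vegetation height band (m).
#' @return The cloud with a `hag` column and vegetation labels.
#' @export
normalize_hag <- function(cloud, cell_size = 0.25, hag_min = 0.05, hag_max = 3.0) {
  g <- cloud$class == "ground"
  if (!any(g)) stop("no ground points: cannot normalize heights", call. = FALSE)
  gx <- cloud$x[g]; gy <- cloud$y[g]; gz <- cloud$z[g]
  x0 <- min(gx); y0 <- min(gy)
  ci <- pmax(1L, ceiling((gx - x0) / cell_size))
  ri <- pmax(1L, ceiling((gy - y0) / cell_size))
  nr <- max(ri); nc <- max(ci)
  surf <- matrix(NA_real_, nr, nc)
  mins <- tapply(gz, (ci - 1L) * nr + ri, min)
  surf[as.integer(names(mins))] <- mins
  # fill empty cells from the nearest filled cell (small grids; exact search)
  if (anyNA(surf)) {
    filled <- which(!is.na(surf), arr.ind = TRUE)
    empty <- which(is.na(surf), arr.ind = TRUE)
    for (k in seq_len(nrow(empty))) {
      d2 <- (filled[, 1L] - empty[k, 1L])^2 + (filled[, 2L] - empty[k, 2L])^2
      surf[empty[k, 1L], empty[k, 2L]] <- surf[filled[which.min(d2), , drop = FALSE]]
    }
  }
  ground_at <- function(px, py) {
    # continuous cell-center coordinates
    fc <- (px - x0) / cell_size + 0.5
    fr <- (py - y0) / cell_size + 0.5
    c1 <- pmin(pmax(floor(fc), 1L), nc); c2 <- pmin(c1 + 1L, nc)
    r1 <- pmin(pmax(floor(fr), 1L), nr); r2 <- pmin(r1 + 1L, nr)
    tx <- pmin(pmax(fc - c1, 0), 1)
    ty <- pmin(pmax(fr - r1, 0), 1)
    v11 <- surf[cbind(r1, c1)]; v12 <- surf[cbind(r1, c2)]
    v21 <- surf[cbind(r2, c1)]; v22 <- surf[cbind(r2, c2)]
    (1 - ty) * ((1 - tx) * v11 + tx * v12) + ty * ((1 - tx) * v21 + tx * v22)
  }
  cloud$hag <- cloud$z - ground_at(cloud$x, cloud$y)
  veg <- cloud$class == "unassigned" & cloud$hag >= hag_min & cloud$hag <= hag_max
  cloud$class[veg] <- "vegetation"
  cloud
}
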