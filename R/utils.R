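# Shared numeric and geometric helpers. Percentile and histogram conventions
# live here so the spectral and structural feature extractors share one
# implementation.

#' Evaluate an expression with a locally seeded RNG
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so package functions never leak changes into the global random state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a root seed and a stage offset, kept within the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

#' Linear-interpolation percentile
#'
#' Percentile with the linear interpolation convention (`stats::quantile`
#' type 7), used for every reported percentile feature (band statistics and
#' canopy height quantiles).
#'
#' @param x Numeric vector.
#' @param p Probabilities in `[0, 1]`.
#' @return Numeric vector of percentiles.
#' @keywords internal
pct_linear <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

# Inverse-ECDF percentile (type 1). Used only by the masking cascade's
# 1st/99th percentile exclusion: for small pixel sets the bounds coincide
# with the extreme order statistics, so strict exclusion removes nothing.
pct_ecdf <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 1, names = FALSE))
}

#' Histogram-shape features of a sample
#'
#' Builds a fixed-bin histogram (equal-width bins spanning the sample range)
#' and summarizes its shape: location of the main peak (modal bin center),
#' frequency of the main peak (modal count / sample size), and distribution
#' width (number of bins with count at least half the modal count, times the
#' bin width). Modal ties are broken toward the lower-valued bin. A constant
#' sample degenerates to `peak_location = value`, `peak_frequency = 1`,
#' `distribution_width = 0`.
#'
#' @param x Numeric vector (length >= 1).
#' @param n_bins Number of equal-width bins (default 50).
#' @return Named list with `peak_location`, `peak_frequency`,
#'   `distribution_width`.
#' @export
#' @examples
#' histogram_shape(c(rep(0.2, 8), 0.6, 0.9))
histogram_shape <- function(x, n_bins = 50L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("histogram_shape: no finite values", call. = FALSE)
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    return(list(peak_location = lo, peak_frequency = 1, distribution_width = 0))
  }
  width <- (hi - lo) / n_bins
  # right-closed bins except the first, as hist() does
  idx <- pmin(pmax(ceiling((x - lo) / width), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  modal <- which.max(counts)  # which.max takes the first (lower) tie
  list(
    peak_location = lo + (modal - 0.5) * width,
    peak_frequency = counts[modal] / length(x),
    distribution_width = sum(counts >= counts[modal] / 2) * width
  )
}

# --- planar geometry ---------------------------------------------------------

# Signed area of a closed ring (shoelace). Positive when counter-clockwise.
ring_signed_area <- function(xy) {
  x <- xy[, 1L]
  y <- xy[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Area of a simple polygon
#'
#' @param xy Two-column matrix of ring vertices (closed or open ring).
#' @return Area in squared coordinate units.
#' @keywords internal
polygon_area <- function(xy) {
  xy <- close_ring(xy, drop = TRUE)
  abs(ring_signed_area(xy))
}

# Drop a duplicated closing vertex (or add one with drop = FALSE).
close_ring <- function(xy, drop = TRUE) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  closed <- n > 1L && all(xy[1L, ] == xy[n, ])
  if (drop && closed) xy[-n, , drop = FALSE]
  else if (!drop && !closed) rbind(xy, xy[1L, ])
  else xy
}

#' Vectorized point-in-polygon test (even-odd ray casting)
#'
#' Points exactly on an edge follow the ray-casting half-open convention
#' (lower/left edges in, upper/right out); pixel centers used by the ROI
#' clipper never coincide with buffered ROI boundaries in practice.
#'
#' @param px,py Point coordinates.
#' @param poly Two-column matrix of polygon vertices (open or closed ring).
#' @return Logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  poly <- close_ring(poly, drop = TRUE)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Inward buffer of a convex polygon
#'
#' Offsets every edge inward by `dist` along its normal and intersects the
#' resulting half-planes (valid for convex rings; quadrat ROIs are convex).
#'
#' @param xy Two-column matrix of vertices, any orientation.
#' @param dist Buffer distance (m), `>= 0`.
#' @return Two-column matrix of the buffered ring, or an error if the buffer
#'   consumes the polygon.
#' @keywords internal
buffer_inward <- function(xy, dist) {
  xy <- close_ring(xy, drop = TRUE)
  if (dist == 0) return(xy)
  if (dist < 0) stop("buffer distance must be >= 0", call. = FALSE)
  if (ring_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  n <- nrow(xy)
  nxt <- c(seq_len(n)[-1L], 1L)
  # for CCW rings the inward normal of edge (p_i -> p_{i+1}) is (-dy, dx)/len
  ex <- xy[nxt, 1L] - xy[, 1L]
  ey <- xy[nxt, 2L] - xy[, 2L]
  len <- sqrt(ex^2 + ey^2)
  if (any(len == 0)) stop("degenerate polygon edge", call. = FALSE)
  ox <- xy[, 1L] - ey / len * dist
  oy <- xy[, 2L] + ex / len * dist
  # intersect consecutive offset edges
  prv <- c(n, seq_len(n - 1L))
  out <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    p <- prv[i]
    # line p: (ox[p],oy[p]) + t*(ex[p],ey[p]); line i: (ox[i],oy[i]) + s*(ex[i],ey[i])
    det <- ex[p] * ey[i] - ey[p] * ex[i]
    if (abs(det) < 1e-12) {  # collinear edges: take the offset vertex
      out[i, ] <- c(ox[i], oy[i])
    } else {
      t <- ((ox[i] - ox[p]) * ey[i] - (oy[i] - oy[p]) * ex[i]) / det
      out[i, ] <- c(ox[p] + t * ex[p], oy[p] + t * ey[p])
    }
  }
  if (ring_signed_area(out) <= 0 || !all(is.finite(out))) {
    stop("inward buffer consumed the polygon", call. = FALSE)
  }
  # every buffered vertex must stay >= dist inside every original edge;
  # an over-large buffer flips edges past each other and violates this
  for (i in seq_len(n)) {
    d_edge <- (ex[i] * (out[, 2L] - xy[i, 2L]) -
                 ey[i] * (out[, 1L] - xy[i, 1L])) / len[i]
    if (any(d_edge < dist - 1e-9)) {
      stop("inward buffer consumed the polygon", call. = FALSE)
    }
  }
  out
}

#' Convex hull area of a 2D point set
#'
#' @param x,y Point coordinates.
#' @return Hull area (0 for fewer than 3 distinct points).
#' @keywords internal
convex_hull_area <- function(x, y) {
  keep <- !duplicated(cbind(x, y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) return(0)
  h <- grDevices::chull(x, y)
  polygon_area(cbind(x[h], y[h]))
}

# Sample skewness and excess kurtosis, bias-uncorrected moment form
# (normal sample -> approximately 0 for both).
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

sample_excess_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2 - 3
}
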