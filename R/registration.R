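# Least-squares bivariate polynomial registration on control-point pairs,
# with RMSE-driven iterative refinement and order selection. Used to align a
# source frame (e.g., a LiDAR orthophoto and its point cloud) to a reference
# frame (the multispectral orthomosaic).

# Monomial exponent table for a given order: terms sorted by total degree
# ascending, then by x-power descending (1, x, y, x^2, xy, y^2, ...).
poly_terms <- function(order) {
  do.call(rbind, lapply(0:order, function(d) cbind(px = d:0, py = 0:d)))
}

n_poly_coeffs <- function(order) (order + 1) * (order + 2) / 2

poly_design <- function(x, y, order) {
  tt <- poly_terms(order)
  m <- matrix(NA_real_, length(x), nrow(tt))
  for (k in seq_len(nrow(tt))) m[, k] <- x^tt[k, "px"] * y^tt[k, "py"]
  m
}

#' Construct a control-point set
#'
#' @param src_x,src_y Source-frame coordinates (m).
#' @param ref_x,ref_y Reference-frame coordinates (m).
#' @param id Optional point labels.
#' @return A `data.frame` of class `control_points`.
#' @export
control_points <- function(src_x, src_y, ref_x, ref_y, id = NULL) {
  n <- length(src_x)
  stopifnot(length(src_y) == n, length(ref_x) == n, length(ref_y) == n)
  if (anyDuplicated(cbind(ref_x, ref_y))) {
    stop("duplicate reference coordinates in control points", call. = FALSE)
  }
  if (is.null(id)) id <- as.character(seq_len(n))
  structure(
    data.frame(id = as.character(id), src_x = src_x, src_y = src_y,
               ref_x = ref_x, ref_y = ref_y, stringsAsFactors = FALSE),
    class = c("control_points", "data.frame")
  )
}

#' Read and write control points as CSV
#'
#' Columns `id, src_x, src_y, ref_x, ref_y`.
#'
#' @param points A `control_points` table.
#' @param path CSV path.
#' @return `read_control_points()` returns a `control_points` table.
#' @export
write_control_points <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_control_points
#' @export
read_control_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  control_points(df$src_x, df$src_y, df$ref_x, df$ref_y, id = df$id)
}

#' Fit a polynomial transform on control points
#'
#' Least-squares bivariate polynomial mapping source to reference
#' coordinates, one coefficient vector per output axis. The reported `rmse`
#' is the root mean square of the residual point distances at the control
#' points.
#'
#' @param points A `control_points` table.
#' @param order Polynomial order (1, 2 or 3).
#' @return An object of class `poly_transform` with `order`, `coeffs_x`,
#'   `coeffs_y`, `rmse`, `n_points`.
#' @export
#' @examples
#' cp <- control_points(c(0, 1, 0, 1, 2, 2, 0.5),
#'                      c(0, 0, 1, 1, 0, 2, 1.5),
#'                      c(0, 1, 0, 1, 2, 2, 0.5) + 2,
#'                      c(0, 0, 1, 1, 0, 2, 1.5) - 1.5)
#' fit_polynomial_transform(cp, order = 1)
fit_polynomial_transform <- function(points, order) {
  if (!order %in% 1:3) stop("`order` must be 1, 2 or 3", call. = FALSE)
  m <- n_poly_coeffs(order)
  n <- nrow(points)
  if (n < m) {
    stop(sprintf("order-%d transform needs at least %d control points (got %d)",
                 order, m, n), call. = FALSE)
  }
  A <- poly_design(points$src_x, points$src_y, order)
  qrA <- qr(A)
  if (qrA$rank < m) {
    stop("rank-deficient design: control points are collinear or degenerate",
         call. = FALSE)
  }
  cx <- qr.coef(qrA, points$ref_x)
  cy <- qr.coef(qrA, points$ref_y)
  pred <- cbind(A %*% cx, A %*% cy)
  res2 <- (pred[, 1L] - points$ref_x)^2 + (pred[, 2L] - points$ref_y)^2
  structure(
    list(order = order, coeffs_x = unname(cx), coeffs_y = unname(cy),
         rmse = sqrt(mean(res2)), n_points = n, converged = TRUE,
         dropped = character(0)),
    class = "poly_transform"
  )
}

#' Apply a polynomial transform to coordinates
#'
#' @param transform A fitted `poly_transform`.
#' @param coords Two-column matrix (or data frame) of source x, y.
#' @return Two-column matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, coords) {
  coords <- as.matrix(coords)
  A <- poly_design(coords[, 1L], coords[, 2L], transform$order)
  cbind(x = as.numeric(A %*% transform$coeffs_x),
        y = as.numeric(A %*% transform$coeffs_y))
}

#' @export
predict.poly_transform <- function(object, coords, ...) apply_transform(object, coords)

#' @export
print.poly_transform <- function(x, ...) {
  cat(sprintf("<poly_transform> order %d, %d control points, rmse %.4g m%s\n",
              x$order, x$n_points, x$rmse,
              if (x$converged) "" else " (not converged)"))
  if (length(x$dropped)) {
    cat("  dropped control points:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Iterative refinement and order selection
#'
#' Evaluates candidate polynomial orders from the lowest up. For each order,
#' the transform is fitted and, while its control-point RMSE exceeds
#' `rmse_threshold`, the single worst-residual point is dropped and the fit
#' repeated (at most `max_drops` drops, never below the order's minimum pair
#' count). The first (lowest-order) transform meeting the threshold is
#' returned; if none does, the best transform seen is returned flagged
#' `converged = FALSE`.
#'
#' @param points A `control_points` table with at least 6 pairs.
#' @param rmse_threshold RMSE target (m); a sensible default is one
#'   reference-raster pixel.
#' @param orders Candidate orders, lowest first (default `1:3`).
#' @param max_drops Maximum control points dropped per order (default 2).
#' @return A `poly_transform`; `$dropped` lists removed point ids.
#' @export
refine_and_select_order <- function(points, rmse_threshold, orders = 1:3,
                                    max_drops = 2L) {
  if (nrow(points) < 6L) stop("need at least 6 control-point pairs", call. = FALSE)
  best <- NULL
  for (ord in sort(orders)) {
    work <- points
    dropped <- character(0)
    for (iter in 0:max_drops) {
      if (nrow(work) < n_poly_coeffs(ord)) break
      fit <- tryCatch(fit_polynomial_transform(work, ord), error = function(e) NULL)
      if (is.null(fit)) break
      fit$dropped <- dropped
      if (fit$rmse <= rmse_threshold) return(fit)
      if (is.null(best) || fit$rmse < best$rmse) best <- fit
      if (iter == max_drops) break
      pred <- apply_transform(fit, work[, c("src_x", "src_y")])
      res <- sqrt((pred[, 1L] - work$ref_x)^2 + (pred[, 2L] - work$ref_y)^2)
      worst <- which.max(res)
      dropped <- c(dropped, work$id[worst])
      work <- work[-worst, , drop = FALSE]
    }
  }
  best$converged <- FALSE
  best
}

#' Serialize a polynomial transform to JSON
#'
#' @param transform A `poly_transform`.
#' @param path JSON path.
#' @return `read_transform()` returns a `poly_transform`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$dropped <- as.character(obj$dropped)
  structure(obj, class = "poly_transform")
}
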