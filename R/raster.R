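# Reflectance raster container and plain-file interchange. Rasters are held
# in memory as named band matrices with a simple north-up geotransform
# (origin at the top-left corner, square pixels). On disk a raster is a
# multi-page TIFF (one 32-bit float page per band) with a JSON sidecar
# carrying the georeferencing, band order and nodata flag.

CANOPYFUSE_BANDS <- c("Blue", "Green", "Red", "RedEdge", "NIR")

#' Construct a five-band reflectance raster
#'
#' @param bands Named list of numeric matrices (`Blue`, `Green`, `Red`,
#'   `RedEdge`, `NIR`), identical dimensions, reflectance nominally in
#'   `[0, 1]`. Rows run north to south.
#' @param origin Numeric length-2: x of the west edge and y of the north edge
#'   of the grid (m).
#' @param pixel_size Pixel side length (m), `> 0`.
#' @param nodata_mask Optional logical matrix marking pixels excluded from
#'   every statistic.
#' @return An object of class `reflectance_raster`.
#' @export
reflectance_raster <- function(bands, origin, pixel_size, nodata_mask = NULL) {
  if (!is.list(bands) || !setequal(names(bands), CANOPYFUSE_BANDS)) {
    stop("`bands` must be a named list with bands ",
         paste(CANOPYFUSE_BANDS, collapse = ", "), call. = FALSE)
  }
  bands <- bands[CANOPYFUSE_BANDS]
  dims <- lapply(bands, dim)
  if (length(unique(dims)) != 1L) stop("all bands must share dimensions", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nrow(bands[[1L]]), ncol(bands[[1L]]))
  stopifnot(identical(dim(nodata_mask), dim(bands[[1L]])))
  structure(
    list(bands = bands, origin = as.numeric(origin), pixel_size = pixel_size,
         nodata_mask = nodata_mask),
    class = "reflectance_raster"
  )
}

#' @export
print.reflectance_raster <- function(x, ...) {
  d <- dim(x$bands[[1L]])
  cat(sprintf("<reflectance_raster> %d x %d px, %d bands, %.3g m/px\n",
              d[1L], d[2L], length(x$bands), x$pixel_size))
  cat(sprintf("  extent: x [%.2f, %.2f], y [%.2f, %.2f] m\n",
              x$origin[1L], x$origin[1L] + d[2L] * x$pixel_size,
              x$origin[2L] - d[1L] * x$pixel_size, x$origin[2L]))
  invisible(x)
}

# Pixel-center coordinates for (row, col) index vectors.
pixel_centers <- function(raster, row, col) {
  cbind(
    x = raster$origin[1L] + (col - 0.5) * raster$pixel_size,
    y = raster$origin[2L] - (row - 0.5) * raster$pixel_size
  )
}

raster_extent <- function(raster) {
  d <- dim(raster$bands[[1L]])
  c(xmin = raster$origin[1L],
    xmax = raster$origin[1L] + d[2L] * raster$pixel_size,
    ymin = raster$origin[2L] - d[1L] * raster$pixel_size,
    ymax = raster$origin[2L])
}

#' Write and read a reflectance raster
#'
#' `write_raster()` stores the bands as a multi-page 32-bit float TIFF and
#' the georeferencing in `<path>.json`; `read_raster()` reverses it.
#'
#' @param raster A `reflectance_raster`.
#' @param path TIFF file path.
#' @return `read_raster()` returns a `reflectance_raster`; `write_raster()`
#'   returns `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  pages <- lapply(raster$bands, function(b) {
    b[raster$nodata_mask] <- -9999
    b
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(
    origin_x = raster$origin[1L], origin_y = raster$origin[2L],
    pixel_size = raster$pixel_size, bands = names(raster$bands),
    nodata = -9999
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  names(pages) <- meta$bands
  mask <- pages[[1L]] == meta$nodata
  pages <- lapply(pages, function(b) {
    b[mask] <- NA_real_
    b
  })
  reflectance_raster(pages, origin = c(meta$origin_x, meta$origin_y),
                     pixel_size = meta$pixel_size, nodata_mask = mask)
}

# --- quadrat ROIs ------------------------------------------------------------

#' Construct a quadrat ROI table
#'
#' Quadrats are the 1 m x 1 m ground sampling units linking the imagery to
#' measured biomass. The table holds one row per quadrat with its metadata;
#' the polygons (planar rings, m) travel as an attribute.
#'
#' @param id Character quadrat identifiers (unique).
#' @param polygons List of two-column vertex matrices, one per quadrat.
#' @param biomass Measured biomass (kg m^-2), `NA` allowed for prediction-only
#'   quadrats.
#' @param stage Growth-stage label per quadrat.
#' @param fertilizer_level Fraction of the conventional fertilizer rate
#'   (one of 0, 0.5, 0.75, 1, 1.25, 1.5).
#' @param batch_date Acquisition batch date (character or Date).
#' @param buffer_width Inward buffer (m) applied before feature extraction;
#'   must lie in `[0.05, 0.10]` (default 0.075).
#' @return A `data.frame` of class `quadrat_rois` with a `polygons` attribute.
#' @export
quadrat_rois <- function(id, polygons, biomass = NA_real_, stage = "unknown",
                         fertilizer_level = 1, batch_date = NA,
                         buffer_width = 0.075) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate quadrat ids", call. = FALSE)
  if (length(polygons) != length(id)) stop("one polygon per id required", call. = FALSE)
  # 5-10 cm in field use; 0 permitted for exact-tiling checks
  if (any(buffer_width < 0 | buffer_width > 0.10)) {
    stop("`buffer_width` must lie in [0, 0.10] m", call. = FALSE)
  }
  df <- data.frame(
    id = id,
    biomass = rep_len(as.numeric(biomass), length(id)),
    stage = rep_len(as.character(stage), length(id)),
    fertilizer_level = rep_len(as.numeric(fertilizer_level), length(id)),
    batch_date = rep_len(as.character(batch_date), length(id)),
    buffer_width = rep_len(as.numeric(buffer_width), length(id)),
    stringsAsFactors = FALSE
  )
  polygons <- lapply(polygons, function(p) close_ring(as.matrix(p), drop = TRUE))
  names(polygons) <- id
  attr(df, "polygons") <- polygons
  class(df) <- c("quadrat_rois", "data.frame")
  df
}

roi_polygon <- function(rois, id) attr(rois, "polygons")[[as.character(id)]]

#' @export
print.quadrat_rois <- function(x, ...) {
  cat(sprintf("<quadrat_rois> %d quadrats (%d with measured biomass)\n",
              nrow(x), sum(!is.na(x$biomass))))
  NextMethod()
}

#' Write and read quadrat ROIs as GeoJSON
#'
#' Polygons become a `FeatureCollection` with properties `id`,
#' `biomass_kg_m2`, `stage`, `fertilizer_level`, `batch_date`,
#' `buffer_width`.
#'
#' @param rois A `quadrat_rois` table.
#' @param path GeoJSON file path.
#' @return `read_rois()` returns a `quadrat_rois`; `write_rois()` returns
#'   `path` invisibly.
#' @export
write_rois <- function(rois, path) {
  polys <- attr(rois, "polygons")
  features <- lapply(seq_len(nrow(rois)), function(i) {
    ring <- close_ring(polys[[rois$id[i]]], drop = FALSE)
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(k) ring[k, ]))),
      properties = list(
        id = rois$id[i], biomass_kg_m2 = rois$biomass[i], stage = rois$stage[i],
        fertilizer_level = rois$fertilizer_level[i],
        batch_date = rois$batch_date[i], buffer_width = rois$buffer_width[i]
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  }
  props <- lapply(gj$features, `[[`, "properties")
  polys <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1L]]
    do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
  })
  get_prop <- function(name, default) {
    vapply(props, function(p) {
      v <- p[[name]]
      if (is.null(v)) default else v
    }, default)
  }
  quadrat_rois(
    id = vapply(props, function(p) as.character(p$id), ""),
    polygons = polys,
    biomass = get_prop("biomass_kg_m2", NA_real_),
    stage = get_prop("stage", "unknown"),
    fertilizer_level = get_prop("fertilizer_level", 1),
    batch_date = get_prop("batch_date", NA_character_),
    buffer_width = get_prop("buffer_width", 0.075)
  )
}
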