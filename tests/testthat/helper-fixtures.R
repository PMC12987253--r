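# Shared fixtures, built in code. Expensive objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A fast ensemble configuration for tests that exercise logic, not accuracy.
light_config <- function() {
  ensemble_config(
    rf = list(n_estimators = 60L),
    et = list(n_estimators = 60L),
    hgb = list(max_iter = 60L)
  )
}

# Build a tiny reflectance raster from per-band constant values or matrices.
make_raster <- function(nrow = 3L, ncol = 3L, pixel_size = 1,
                        Blue = 0.05, Green = 0.2, Red = 0.1, RedEdge = 0.3,
                        NIR = 0.5, origin = c(0, nrow * pixel_size)) {
  as_band <- function(v) if (is.matrix(v)) v else matrix(v, nrow, ncol)
  reflectance_raster(
    list(Blue = as_band(Blue), Green = as_band(Green), Red = as_band(Red),
         RedEdge = as_band(RedEdge), NIR = as_band(NIR)),
    origin = origin, pixel_size = pixel_size
  )
}

# A single square ROI.
square_roi <- function(xmin, ymin, side, buffer_width = 0.075, id = "Q1", ...) {
  quadrat_rois(
    id = id,
    polygons = list(rbind(c(xmin, ymin), c(xmin + side, ymin),
                          c(xmin + side, ymin + side), c(xmin, ymin + side))),
    buffer_width = buffer_width, ...
  )
}

# Subset a quadrat_rois table, keeping polygons and class.
subset_rois <- function(rois, idx) {
  out <- rois[idx, , drop = FALSE]
  attr(out, "polygons") <- attr(rois, "polygons")
  class(out) <- class(rois)
  out
}

# Small scene + features reused by feature-table / ensemble / pipeline tests.
small_scene <- function() {
  cached("small_scene", generate_scene(scene_config(n_quadrats = 40L, seed = 101L)))
}

small_features <- function() {
  cached("small_features", {
    sc <- small_scene()
    extract_features(sc$raster, sc$cloud, sc$quadrats)
  })
}

# Plain feature table with a planted linear signal, for model-level tests.
planted_table <- function(n = 120L, p = 6L, noise = 0.1, seed = 7L) {
  canopyfuse:::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
    df <- as.data.frame(X)
    df$biomass <- X[, 1L] + 0.6 * X[, 2L] + 0.3 * X[, 3L] + rnorm(n, 0, noise)
    prov <- stats::setNames(rep("spectral", p), colnames(X))
    canopyfuse:::as_feature_table(cbind(id = as.character(seq_len(n)), df), prov)
  })
}
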