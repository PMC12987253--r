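# Per-quadrat feature fusion: spectral + structural + geometric + treatment
# columns, interaction features, impurity-based importance and
# cumulative-contribution selection.

META_COLUMNS <- c("id", "batch_date", "stage", "biomass")

#' Extract the fused feature table of a scene
#'
#' Runs the full per-quadrat extraction: spectral features through the
#' masking cascade, point-cloud preparation (statistical outlier removal,
#' progressive morphological ground classification, HAG normalization) on a
#' window around each quadrat, structural features, treatment metadata and
#' interaction features. Quadrats whose ROI is sparse in vegetation points
#' get `NA` structural features and a raised `structural_absent` indicator.
#'
#' @param raster A `reflectance_raster`.
#' @param cloud A `canopy_cloud` (raw; classified per quadrat window).
#' @param rois A `quadrat_rois` table.
#' @param cloud_margin Margin (m) around the buffered ROI used as ground
#'   context for classification (default 0.6).
#' @param interactions Append interaction features (default TRUE).
#' @param k_neighbors,sd_multiplier Outlier filter parameters.
#' @param cell_size Ground grid cell size (m).
#' @param ... Passed to [spectral_features()].
#' @return A `feature_table`: data frame with metadata columns (`id`,
#'   `batch_date`, `stage`, `biomass`) and numeric feature columns;
#'   provenance (feature -> source) and mask reports as attributes.
#' @export
extract_features <- function(raster, cloud, rois, cloud_margin = 0.6,
                             interactions = TRUE, k_neighbors = 8L,
                             sd_multiplier = 3, cell_size = 0.25, ...) {
  rows <- vector("list", nrow(rois))
  reports <- vector("list", nrow(rois))
  names(reports) <- rois$id
  for (i in seq_len(nrow(rois))) {
    id <- rois$id[i]
    spec <- spectral_features(raster, rois, id, ...)
    reports[[id]] <- spec$report

    poly <- roi_polygon(rois, id)
    sub <- crop_cloud(cloud,
                      min(poly[, 1L]) - cloud_margin, max(poly[, 1L]) + cloud_margin,
                      min(poly[, 2L]) - cloud_margin, max(poly[, 2L]) + cloud_margin)
    struct <- if (nrow(sub) >= k_neighbors + 2L) {
      sub <- remove_outliers(sub, k_neighbors = k_neighbors,
                             sd_multiplier = sd_multiplier)
      sub <- classify_ground(sub, cell_size = cell_size)
      sub <- normalize_hag(sub, cell_size = cell_size)
      structural_features(sub, rois, id)
    } else {
      c(stats::setNames(as.list(rep(NA_real_, length(STRUCTURAL_FEATURES))),
                        STRUCTURAL_FEATURES),
        list(n_vegetation = nrow(sub), sparse = TRUE))
    }
    sf <- unlist(struct[STRUCTURAL_FEATURES])
    rows[[i]] <- c(spec$features, sf,
                   structural_absent = as.numeric(struct$sparse))
  }
  feats <- do.call(rbind, rows)
  tab <- data.frame(
    id = rois$id, batch_date = rois$batch_date, stage = rois$stage,
    biomass = rois$biomass, fertilizer_level = rois$fertilizer_level,
    feats, stringsAsFactors = FALSE, check.names = FALSE
  )
  spectral_cols <- setdiff(names(spec$features),
                           c("roi_area_m2", "count_valid_pixels", "count_total_pixels"))
  prov <- c(
    stats::setNames(rep("spectral", length(spectral_cols)), spectral_cols),
    roi_area_m2 = "geometry", count_valid_pixels = "geometry",
    count_total_pixels = "geometry",
    stats::setNames(rep("structural", length(STRUCTURAL_FEATURES)),
                    STRUCTURAL_FEATURES),
    structural_absent = "indicator", fertilizer_level = "treatment"
  )
  tab <- as_feature_table(tab, prov)
  attr(tab, "mask_reports") <- reports
  if (interactions) tab <- build_interaction_features(tab)
  tab
}

as_feature_table <- function(df, provenance) {
  if (anyDuplicated(df$id)) stop("duplicated quadrat ids", call. = FALSE)
  attr(df, "provenance") <- provenance
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Feature column names of a feature table
#'
#' @param table A `feature_table`.
#' @param source Optional provenance filter (`"spectral"`, `"structural"`,
#'   `"geometry"`, `"treatment"`, `"interaction"`, `"indicator"`).
#' @return Character vector of column names.
#' @export
feature_columns <- function(table, source = NULL) {
  prov <- attr(table, "provenance")
  cols <- names(prov)[names(prov) %in% names(table)]
  if (!is.null(source)) cols <- cols[prov[cols] %in% source]
  cols
}

#' @export
print.feature_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<feature_table> %d quadrats x %d features (%s)\n",
              nrow(x), length(feature_columns(x)),
              paste(sprintf("%s %d", names(table(prov)), table(prov)), collapse = ", ")))
  invisible(x)
}

#' Append structure-by-spectrum interaction features
#'
#' Appends the pairwise products of canopy height percentiles with
#' vegetation index means and of vertical stratification proportions with
#' vegetation index means, named `a_X_b`.
#'
#' @param table A `feature_table`.
#' @param structure_cols Height percentile and stratum columns (defaults to
#'   `Hq05`...`Hq95` and the four strata proportions present in the table).
#' @param spectral_cols Vegetation index columns (defaults to the six index
#'   means).
#' @return The table with interaction columns appended to the provenance.
#' @export
build_interaction_features <- function(table,
                                       structure_cols = NULL,
                                       spectral_cols = NULL) {
  if (is.null(structure_cols)) {
    structure_cols <- intersect(
      c("Hq05", "Hq10", "Hq25", "Hq50", "Hq75", "Hq90", "Hq95",
        "strata_0p0_0p5", "strata_0p5_1p0", "strata_1p0_1p5", "strata_1p5_3p0"),
      names(table))
  }
  if (is.null(spectral_cols)) {
    spectral_cols <- intersect(c("NDVI", "NDRE", "GNDVI", "MSR", "EVI", "SAVI"),
                               names(table))
  }
  missing <- setdiff(c(structure_cols, spectral_cols), names(table))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  prov <- attr(table, "provenance")
  for (a in structure_cols) {
    for (b in spectral_cols) {
      nm <- paste0(a, "_X_", b)
      if (nm %in% names(table)) stop("interaction name collision: ", nm, call. = FALSE)
      table[[nm]] <- table[[a]] * table[[b]]
      prov[nm] <- "interaction"
    }
  }
  as_feature_table(table, prov)
}

#' Impurity-based feature importance of a table
#'
#' Fits an [impurity_forest()] of the table's features against biomass and
#' returns the normalized importance ranking (descending, ties broken by
#' feature name).
#'
#' @param table A `feature_table` with measured biomass.
#' @param forest_config Named list overriding [impurity_forest()] defaults.
#' @param seed Integer seed.
#' @return An `importance_ranking`: data frame (`feature`, `importance`)
#'   sorted by importance, with the fitted forest as attribute `forest`.
#' @export
impurity_importance <- function(table, forest_config = list(), seed = 1L) {
  rows <- !is.na(table$biomass)
  if (sum(rows) < 20L) stop("need at least 20 training rows", call. = FALSE)
  cols <- feature_columns(table)
  X <- prepare_matrix(table[rows, , drop = FALSE], cols)
  if (anyNA(X)) {  # sparse-ROI structural features: median imputation
    med <- apply(X, 2L, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0
    X <- impute_with(X, med)
  }
  forest <- do.call(impurity_forest,
                    c(list(X = X, y = table$biomass[rows], seed = seed),
                      forest_config))
  fi <- forest$importance
  ord <- order(-fi, names(fi))
  out <- data.frame(feature = names(fi)[ord], importance = unname(fi[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "forest") <- forest
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("<importance_ranking> %d features, top: %s\n", nrow(x),
              paste(sprintf("%s %.3f", utils::head(x$feature, 3L),
                            utils::head(x$importance, 3L)), collapse = ", ")))
  invisible(x)
}

#' Write an importance ranking as CSV
#'
#' @param ranking An `importance_ranking`.
#' @param path CSV path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE)
  invisible(path)
}

#' Select features by cumulative importance
#'
#' Sorts features by importance (descending, ties by name) and returns the
#' shortest prefix whose cumulative normalized importance reaches
#' `threshold`.
#'
#' @param ranking An `importance_ranking` (or data frame with `feature`,
#'   `importance`).
#' @param threshold Cumulative contribution target in `(0, 1]` (default 0.95).
#' @return Character vector of selected feature names.
#' @export
select_by_cumulative_importance <- function(ranking, threshold = 0.95) {
  if (nrow(ranking) == 0L) stop("empty importance ranking", call. = FALSE)
  ord <- order(-ranking$importance, ranking$feature)
  fi <- ranking$importance[ord] / sum(ranking$importance)
  k <- which(cumsum(fi) >= threshold - 1e-12)[1L]
  if (is.na(k)) k <- length(fi)
  ranking$feature[ord][seq_len(k)]
}

# Numeric model matrix for the given columns; feature-table round trip and
# fits share it. NAs are allowed here and handled by the imputation step.
prepare_matrix <- function(table, cols) {
  X <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Write and read a feature table (CSV + JSON schema sidecar)
#'
#' The sidecar (`<path>.schema.json`) records each feature's provenance so a
#' reloaded table keeps its column grouping.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return `read_feature_table()` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(as.list(attr(table, "provenance")),
                       paste0(path, ".schema.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  prov <- unlist(jsonlite::read_json(paste0(path, ".schema.json"),
                                     simplifyVector = TRUE))
  as_feature_table(df, prov)
}
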