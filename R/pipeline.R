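# End-to-end orchestration: generate or load a scene, optionally register
# the point cloud onto the raster frame, extract and fuse features, rank and
# select them, train the weighted ensemble and evaluate it. Every stage
# persists its artifact under the run directory, and a machine-readable run
# log records seeds, versions and stage order.

PIPELINE_KEYS <- c("synthetic", "paths", "registration", "extraction",
                   "selection", "model", "split", "seed", "out_dir")

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (typically read from YAML) with keys:
#' `synthetic` (arguments for [scene_config()]) or `paths` (files
#' `raster`, `cloud`, `rois`), optional `registration` (`control_points`
#' CSV + `rmse_threshold`), `extraction`, `selection`
#' (`threshold`, `forest` overrides), `model` (`rf` / `et` / `hgb`
#' overrides, `n_folds`, `weight_step`), `split` (`train_fraction`),
#' `seed` and `out_dir`. Unknown keys are rejected before any computation.
#'
#' @param config Named list.
#' @return The validated config with defaults filled, invisibly usable.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$synthetic) && is.null(config$paths)) {
    stop("config needs either `synthetic` or `paths`", call. = FALSE)
  }
  if (!is.null(config$paths)) {
    need <- setdiff(c("raster", "cloud", "rois"), names(config$paths))
    if (length(need)) {
      stop("config `paths` missing: ", paste(need, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  if (is.null(config$split$train_fraction)) config$split$train_fraction <- 0.85
  if (is.null(config$selection$threshold)) config$selection$threshold <- 0.95
  config
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the full biomass pipeline
#'
#' Executes generate/load, optional registration, feature extraction and
#' fusion, importance ranking and cumulative selection, train/test split,
#' ensemble training and evaluation, persisting every intermediate artifact
#' under `config$out_dir`. Any stage error halts the run with the stage
#' name; artifacts persisted before the failure remain on disk.
#'
#' @param config A validated run configuration (see
#'   [validate_run_config()]), or a path to a YAML file.
#' @return Invisibly, a list with the run artifacts (`scene` or inputs,
#'   `features`, `ranking`, `selected`, `model`, `report`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  log <- list(package = "canopyfuse",
              version = as.character(utils::packageVersion("canopyfuse")),
              r_version = as.character(getRversion()),
              seed = seed, stages = character(0))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log$stages <<- c(log$stages, name)
    res
  }

  inputs <- stage("load", {
    if (!is.null(config$synthetic)) {
      sc <- do.call(scene_config, c(config$synthetic, list(seed = seed)))
      scene <- generate_scene(sc)
      write_scene(scene, file.path(out_dir, "scene"))
      list(raster = scene$raster, cloud = scene$cloud, rois = scene$quadrats,
           scene = scene)
    } else {
      for (f in unlist(config$paths)) {
        if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
      }
      list(raster = read_raster(config$paths$raster),
           cloud = read_cloud(config$paths$cloud),
           rois = read_rois(config$paths$rois))
    }
  })

  if (!is.null(config$registration)) {
    inputs$cloud <- stage("register", {
      cp <- read_control_points(config$registration$control_points)
      thr <- config$registration$rmse_threshold
      if (is.null(thr)) thr <- inputs$raster$pixel_size
      tr <- refine_and_select_order(cp, rmse_threshold = thr)
      write_transform(tr, file.path(out_dir, "transform.json"))
      xy <- apply_transform(tr, cbind(inputs$cloud$x, inputs$cloud$y))
      cl <- inputs$cloud
      cl$x <- xy[, 1L]
      cl$y <- xy[, 2L]
      cl
    })
  }

  features <- stage("extract", {
    tab <- do.call(extract_features,
                   c(list(raster = inputs$raster, cloud = inputs$cloud,
                          rois = inputs$rois), config$extraction))
    write_feature_table(tab, file.path(out_dir, "feature_table.csv"))
    reports <- attr(tab, "mask_reports")
    jsonlite::write_json(lapply(reports, unclass),
                         file.path(out_dir, "mask_reports.json"),
                         auto_unbox = TRUE)
    tab
  })

  ranking <- stage("rank", {
    rk <- impurity_importance(features, forest_config = config$selection$forest,
                              seed = derive_seed(seed, 100L))
    write_ranking(rk, file.path(out_dir, "importance.csv"))
    rk
  })
  selected <- stage("select", {
    sel <- select_by_cumulative_importance(ranking, config$selection$threshold)
    jsonlite::write_json(sel, file.path(out_dir, "selected_features.json"))
    sel
  })

  parts <- stage("split", {
    split_train_test(features, train_fraction = config$split$train_fraction,
                     seed = seed)
  })

  model <- stage("train", {
    overrides <- config$model[intersect(names(config$model), c("rf", "et", "hgb"))]
    cfg <- do.call(ensemble_config, as.list(overrides))
    n_folds <- if (is.null(config$model$n_folds)) 10L else config$model$n_folds
    step <- if (is.null(config$model$weight_step)) 0.05 else config$model$weight_step
    fit <- biomass_ensemble(parts$train, features = selected, config = cfg,
                            n_folds = n_folds, weight_step = step, seed = seed)
    write_ensemble(fit, file.path(out_dir, "model"))
    fit
  })

  report <- stage("evaluate", {
    pred <- predict(model, parts$test)
    utils::write.csv(data.frame(id = parts$test$id, observed = parts$test$biomass,
                                predicted_biomass = pred),
                     file.path(out_dir, "predictions.csv"), row.names = FALSE)
    if (nrow(parts$test) >= 8L) {
      rep <- evaluation_report(parts$test$biomass, pred)
      write_report(rep, file.path(out_dir, "evaluation.json"))
    } else {
      # test set too small for distributional diagnostics: metrics only
      rep <- c(regression_metrics(parts$test$biomass, pred),
               list(n = nrow(parts$test), low_confidence = TRUE))
      jsonlite::write_json(rep, file.path(out_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    rep
  })

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  invisible(list(inputs = inputs, features = features, ranking = ranking,
                 selected = selected, split = parts, model = model,
                 report = report, out_dir = out_dir))
}
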