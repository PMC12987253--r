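# Weighted soft-voting ensemble of three heterogeneous tree regressors:
# random forest (RF), extremely randomized trees (ET) and histogram gradient
# boosting (HGB). Features are robust-scaled (median / IQR) before every
# sub-model; the ensemble prediction is the convex combination
#     yhat = w_RF yhat_RF + w_ET yhat_ET + w_HGB yhat_HGB
# with the weight vector chosen on the simplex from out-of-fold predictions
# on the training data only.

#' Robust scaling parameters
#'
#' Per-feature center (median) and scale (interquartile range, substituted
#' by 1 when the IQR is zero).
#'
#' @param X Numeric matrix.
#' @return List of class `robust_scale` with `center` and `scale`.
#' @export
robust_scale_params <- function(X) {
  center <- apply(X, 2L, stats::median, na.rm = TRUE)
  scale <- apply(X, 2L, function(v) {
    q <- pct_linear(v[!is.na(v)], c(0.25, 0.75))
    iqr <- q[2L] - q[1L]
    if (iqr > 0) iqr else 1
  })
  structure(list(center = center, scale = scale), class = "robust_scale")
}

apply_robust_scale <- function(params, X) {
  sweep(sweep(X, 2L, params$center, "-"), 2L, params$scale, "/")
}

#' Seeded train/test split
#'
#' Uniform random split without stratification; the training size is
#' `floor(train_fraction * n)` (270 rows at 0.85 give exactly 229 train and
#' 41 test).
#'
#' @param table A data frame (typically a `feature_table`).
#' @param train_fraction Training proportion in `(0, 1)` (default 0.85).
#' @param seed Integer seed.
#' @return List with `train` and `test` subsets (attributes preserved).
#' @export
split_train_test <- function(table, train_fraction = 0.85, seed = 1L) {
  n <- nrow(table)
  if (n < 20L) stop("need at least 20 rows to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie in (0, 1)", call. = FALSE)
  }
  n_train <- floor(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  keep_attrs <- function(sub) {
    attr(sub, "provenance") <- attr(table, "provenance")
    class(sub) <- class(table)
    sub
  }
  list(train = keep_attrs(table[sort(idx), , drop = FALSE]),
       test = keep_attrs(table[setdiff(seq_len(n), idx), , drop = FALSE]))
}

#' Base-learner hyperparameters
#'
#' Defaults are the tuned configuration: RF with 1000 trees, depth 15,
#' minimum split 5, minimum leaf 2, sqrt feature subsampling; ET with 1200
#' trees, unlimited depth, minimum split 4, minimum leaf 1, no bootstrap;
#' HGB with 1000 boosting iterations, learning rate 0.05, depth 8, minimum
#' leaf 5 and L2 regularization 1.
#'
#' @param rf,et,hgb Named lists overriding individual entries.
#' @return List of class `ensemble_config`.
#' @export
ensemble_config <- function(rf = list(), et = list(), hgb = list()) {
  base <- list(
    rf = list(n_estimators = 1000L, max_depth = 15L, min_samples_split = 5L,
              min_samples_leaf = 2L, max_features = "sqrt"),
    et = list(n_estimators = 1200L, max_depth = 0L, min_samples_split = 4L,
              min_samples_leaf = 1L, max_features = "sqrt"),
    hgb = list(max_iter = 1000L, learning_rate = 0.05, max_depth = 8L,
               min_samples_leaf = 5L, l2_regularization = 1)
  )
  base$rf[names(rf)] <- rf
  base$et[names(et)] <- et
  base$hgb[names(hgb)] <- hgb
  structure(base, class = "ensemble_config")
}

mtry_from <- function(max_features, p) {
  if (identical(max_features, "sqrt")) max(1L, floor(sqrt(p)))
  else max(1L, min(p, as.integer(max_features)))
}

# Fit one base learner on a scaled matrix. `kind` in rf / et / hgb.
fit_base_learner <- function(kind, X, y, hp, seed) {
  p <- ncol(X)
  if (kind == "rf") {
    fit <- ranger::ranger(
      x = X, y = y, num.trees = hp$n_estimators,
      mtry = mtry_from(hp$max_features, p),
      min.node.size = hp$min_samples_split, min.bucket = hp$min_samples_leaf,
      max.depth = hp$max_depth, replace = TRUE, sample.fraction = 1,
      num.threads = 1L, seed = seed, oob.error = FALSE
    )
  } else if (kind == "et") {
    fit <- ranger::ranger(
      x = X, y = y, num.trees = hp$n_estimators,
      mtry = mtry_from(hp$max_features, p),
      min.node.size = hp$min_samples_split, min.bucket = hp$min_samples_leaf,
      max.depth = hp$max_depth, splitrule = "extratrees", num.random.splits = 1L,
      replace = FALSE, sample.fraction = 1,
      num.threads = 1L, seed = seed, oob.error = FALSE
    )
  } else if (kind == "hgb") {
    fit <- with_seed(seed, xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = hp$learning_rate,
                    max_depth = hp$max_depth,
                    min_child_weight = hp$min_samples_leaf,
                    lambda = hp$l2_regularization,
                    tree_method = "hist", nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = hp$max_iter,
      verbose = 0
    ))
  } else {
    stop("unknown base learner: ", kind, call. = FALSE)
  }
  fit
}

predict_base_learner <- function(kind, fit, X) {
  if (kind %in% c("rf", "et")) {
    stats::predict(fit, data = X, num.threads = 1L)$predictions
  } else {
    stats::predict(fit, xgboost::xgb.DMatrix(X))
  }
}

# Candidate weight vectors: simplex grid with the given step plus the exact
# equal-weights point. Ties in out-of-fold score are broken toward equal
# weights, then lexicographically.
simplex_candidates <- function(step = 0.05) {
  w1 <- seq(0, 1, by = step)
  grid <- expand.grid(w_rf = w1, w_et = w1)
  grid <- grid[grid$w_rf + grid$w_et <= 1 + 1e-12, ]
  grid$w_hgb <- pmax(0, 1 - grid$w_rf - grid$w_et)
  cand <- as.matrix(grid[, c("w_rf", "w_et", "w_hgb")])
  rbind(cand, c(1, 1, 1) / 3)
}

r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

# Pick the simplex weight vector maximizing R2 of the combined out-of-fold
# predictions. Exact score ties break toward equal weights, then
# lexicographically.
select_ensemble_weights <- function(oof, y, step = 0.05) {
  cand <- simplex_candidates(step)
  scores <- apply(cand, 1L, function(w) r_squared(y, as.numeric(oof %*% w)))
  ties <- which(scores >= max(scores) - 1e-12)
  if (length(ties) > 1L) {
    d_eq <- rowSums((cand[ties, , drop = FALSE] - 1 / 3)^2)
    ties <- ties[order(d_eq, cand[ties, 1L], cand[ties, 2L])]
  }
  cand[ties[1L], ]
}

#' Fit the weighted soft-voting biomass ensemble
#'
#' Fits the robust scaler on the training rows only, trains RF, ET and HGB
#' on the scaled features, and picks the simplex weight vector maximizing
#' the out-of-fold R-squared of the weighted combination over a grid (step
#' `weight_step`), using `n_folds`-fold out-of-fold predictions on the
#' training set. Ties are broken toward equal weights. Missing structural
#' features are imputed by the training-set median before scaling (the
#' `structural_absent` indicator keeps the information).
#'
#' @param train A `feature_table` (or data frame) of training rows with a
#'   `biomass` column.
#' @param features Character vector of feature columns (default: every
#'   feature column of the table).
#' @param config An [ensemble_config()].
#' @param n_folds Folds for the out-of-fold weight search (default 10).
#' @param weight_step Simplex grid step (default 0.05).
#' @param seed Root seed; fold assignment and each learner derive their own
#'   seeds from it.
#' @return An object of class `biomass_ensemble` with components `learners`,
#'   `weights`, `scaler`, `impute_medians`, `features`, `oof`
#'   (per-learner and ensemble out-of-fold predictions and R-squared) and
#'   `config`.
#' @export
#' @examples
#' \donttest{
#' scene <- generate_scene(scene_config(n_quadrats = 40, seed = 7))
#' tab <- extract_features(scene$raster, scene$cloud, scene$quadrats)
#' parts <- split_train_test(tab, seed = 7)
#' fit <- biomass_ensemble(parts$train, seed = 7,
#'                         config = ensemble_config(rf = list(n_estimators = 100),
#'                                                  et = list(n_estimators = 100),
#'                                                  hgb = list(max_iter = 100)))
#' predict(fit, parts$test)
#' }
biomass_ensemble <- function(train, features = NULL, config = ensemble_config(),
                             n_folds = 10L, weight_step = 0.05, seed = 1L) {
  if (is.null(features)) {
    features <- if (inherits(train, "feature_table")) feature_columns(train)
                else setdiff(names(train), META_COLUMNS)
  }
  missing <- setdiff(features, names(train))
  if (length(missing)) {
    stop("missing feature columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  y <- train$biomass
  if (anyNA(y)) stop("training rows must have measured biomass", call. = FALSE)
  X <- prepare_matrix(train, features)
  impute_medians <- apply(X, 2L, stats::median, na.rm = TRUE)
  impute_medians[is.na(impute_medians)] <- 0
  X <- impute_with(X, impute_medians)
  scaler <- robust_scale_params(X)
  Xs <- apply_robust_scale(scaler, X)
  bad <- !apply(is.finite(Xs), 2L, all)
  if (any(bad)) {
    stop("non-finite features after scaling: ",
         paste(colnames(Xs)[bad], collapse = ", "), call. = FALSE)
  }
  n <- nrow(Xs)
  kinds <- c("rf", "et", "hgb")

  folds <- with_seed(derive_seed(seed, 1L),
                     sample(rep_len(seq_len(n_folds), n)))
  oof <- matrix(NA_real_, n, 3L, dimnames = list(NULL, kinds))
  for (f in seq_len(n_folds)) {
    hold <- folds == f
    if (!any(hold) || all(hold)) next
    for (k in kinds) {
      fit_k <- fit_base_learner(k, Xs[!hold, , drop = FALSE], y[!hold],
                                config[[k]], seed = derive_seed(seed, 10L + f))
      oof[hold, k] <- predict_base_learner(k, fit_k, Xs[hold, , drop = FALSE])
    }
  }

  weights <- select_ensemble_weights(oof, y, step = weight_step)
  names(weights) <- kinds

  learners <- stats::setNames(lapply(kinds, function(k) {
    fit_base_learner(k, Xs, y, config[[k]], seed = derive_seed(seed, 2L))
  }), kinds)

  structure(
    list(learners = learners, weights = weights, scaler = scaler,
         impute_medians = impute_medians, features = features,
         oof = list(predictions = oof, folds = folds,
                    r2_base = apply(oof, 2L, function(p) r_squared(y, p)),
                    r2_ensemble = r_squared(y, oof %*% weights)),
         train_y = y, config = config, n_folds = n_folds,
         weight_step = weight_step, seed = seed),
    class = "biomass_ensemble"
  )
}

impute_with <- function(X, medians) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- medians[j]
  }
  X
}

#' Predict biomass for new quadrats
#'
#' Applies the train-fitted imputation, scaling and base learners, then the
#' convex weight combination.
#'
#' @param object A fitted `biomass_ensemble`.
#' @param newdata Data frame containing the model's feature columns.
#' @param per_learner Also return the per-learner predictions (default
#'   FALSE).
#' @param ... Unused.
#' @return Numeric vector of predicted biomass (kg m^-2), or a matrix with
#'   per-learner columns when `per_learner = TRUE`.
#' @export
predict.biomass_ensemble <- function(object, newdata, per_learner = FALSE, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("newdata is missing feature columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- prepare_matrix(newdata, object$features)
  X <- impute_with(X, object$impute_medians)
  Xs <- apply_robust_scale(object$scaler, X)
  base <- vapply(names(object$learners), function(k) {
    predict_base_learner(k, object$learners[[k]], Xs)
  }, numeric(nrow(Xs)))
  if (nrow(Xs) == 1L) base <- matrix(base, nrow = 1L,
                                     dimnames = list(NULL, names(object$learners)))
  yhat <- as.numeric(base %*% object$weights)
  if (per_learner) cbind(base, ensemble = yhat) else yhat
}

#' @export
coef.biomass_ensemble <- function(object, ...) object$weights

#' @export
residuals.biomass_ensemble <- function(object, ...) {
  # out-of-fold residuals, observed minus predicted
  object$train_y - as.numeric(object$oof$predictions %*% object$weights)
}

#' @export
print.biomass_ensemble <- function(x, ...) {
  cat("<biomass_ensemble> RF + ET + HGB weighted soft voting\n")
  cat(sprintf("  weights: RF %.2f, ET %.2f, HGB %.2f\n",
              x$weights[1L], x$weights[2L], x$weights[3L]))
  cat(sprintf("  %d features, %d training rows, out-of-fold R2 %.3f\n",
              length(x$features), length(x$train_y), x$oof$r2_ensemble))
  invisible(x)
}

#' @export
summary.biomass_ensemble <- function(object, ...) {
  out <- list(
    weights = object$weights,
    r2_base = object$oof$r2_base,
    r2_ensemble = object$oof$r2_ensemble,
    n_train = length(object$train_y),
    n_features = length(object$features)
  )
  class(out) <- "summary.biomass_ensemble"
  out
}

#' @export
print.summary.biomass_ensemble <- function(x, ...) {
  cat("Weighted soft-voting ensemble (RF + ET + HGB)\n")
  cat(sprintf("  training rows: %d, features: %d\n", x$n_train, x$n_features))
  cat("  out-of-fold R2 per learner:\n")
  for (k in names(x$r2_base)) cat(sprintf("    %-4s %.3f (weight %.2f)\n",
                                          k, x$r2_base[k], x$weights[k]))
  cat(sprintf("  out-of-fold R2, weighted ensemble: %.3f\n", x$r2_ensemble))
  invisible(x)
}

#' @export
plot.biomass_ensemble <- function(x, ...) {
  pred <- as.numeric(x$oof$predictions %*% x$weights)
  graphics::plot(x$train_y, pred,
                 xlab = expression(paste("observed biomass (kg ", m^-2, ")")),
                 ylab = expression(paste("out-of-fold predicted (kg ", m^-2, ")")),
                 main = "Biomass ensemble: out-of-fold fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Grid search with k-fold cross-validation for one base learner
#'
#' Exhaustive evaluation of a hyperparameter grid by mean out-of-fold
#' R-squared with deterministic fold assignment.
#'
#' @param X Numeric feature matrix (already scaled).
#' @param y Numeric target.
#' @param kind One of `"rf"`, `"et"`, `"hgb"`.
#' @param param_grid Named list of hyperparameter vectors to cross.
#' @param n_folds Folds (default 10).
#' @param seed Integer seed.
#' @return List with `best` (hyperparameter list), `best_score`, and
#'   `results` (data frame of all grid points with mean CV R-squared).
#' @export
grid_search_cv <- function(X, y, kind, param_grid, n_folds = 10L, seed = 1L) {
  if (length(param_grid) == 0L || any(lengths(param_grid) == 0L)) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  grid <- expand.grid(param_grid, stringsAsFactors = FALSE)
  folds <- with_seed(derive_seed(seed, 1L),
                     sample(rep_len(seq_len(n_folds), nrow(X))))
  base_hp <- ensemble_config()[[kind]]
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- base_hp
    hp[names(grid)] <- as.list(grid[g, , drop = FALSE])
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(n_folds)) {
      hold <- folds == f
      if (!any(hold) || all(hold)) next
      fit <- fit_base_learner(kind, X[!hold, , drop = FALSE], y[!hold], hp,
                              seed = derive_seed(seed, 10L + f))
      oof[hold] <- predict_base_learner(kind, fit, X[hold, , drop = FALSE])
    }
    scores[g] <- r_squared(y[!is.na(oof)], oof[!is.na(oof)])
  }
  grid$cv_r2 <- scores
  best <- which.max(scores)
  hp <- base_hp
  hp[names(param_grid)] <- as.list(grid[best, names(param_grid), drop = FALSE])
  list(best = hp, best_score = scores[best], results = grid)
}

#' Serialize a fitted ensemble to a directory
#'
#' Writes a JSON manifest (weights, scaler, features, seed, hyperparameters,
#' imputation medians) plus one binary blob per learner. The blobs are
#' scratch artifacts for reuse within a session, not interchange files.
#'
#' @param model A `biomass_ensemble`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    weights = as.list(model$weights),
    scaler = list(center = as.list(model$scaler$center),
                  scale = as.list(model$scaler$scale)),
    impute_medians = as.list(model$impute_medians),
    features = model$features, seed = model$seed,
    n_folds = model$n_folds, weight_step = model$weight_step,
    config = lapply(unclass(model$config), function(x) x),
    oof_r2 = list(base = as.list(model$oof$r2_base),
                  ensemble = model$oof$r2_ensemble)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) readRDS(file.path(dir, "model.rds"))
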