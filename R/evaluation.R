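# Metrics and diagnostics: R2 / RMSE / MAE, residual distribution
# statistics, quartile-group and biomass-interval stratified errors,
# per-stage metrics, feature-combination comparison and top-k ablation.
# Residual sign convention throughout: observed minus predicted, so
# underestimation yields a positive residual.

#' Regression metrics
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`, `MAE = mean(|y - yhat|)`.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return Named list with `R2`, `RMSE`, `MAE`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(1.1, 1.9, 3.2))
regression_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  if (length(observed) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (stats::var(observed) == 0) {
    stop("constant observed values: R2 undefined", call. = FALSE)
  }
  err <- observed - predicted
  list(R2 = 1 - sum(err^2) / sum((observed - mean(observed))^2),
       RMSE = sqrt(mean(err^2)),
       MAE = mean(abs(err)))
}

#' Residual distribution diagnostics
#'
#' Residual mean and standard deviation, bias-uncorrected sample skewness
#' and excess kurtosis (normal residuals give approximately 0 for both),
#' absolute-residual bin proportions with cut points 0.1 / 0.2 / 0.3
#' kg m^-2, and theoretical-vs-sample normal quantile pairs for a Q-Q plot.
#'
#' @param observed,predicted Numeric vectors (n >= 8).
#' @param cuts Absolute-residual cut points (default `c(0.1, 0.2, 0.3)`).
#' @return List with `residuals`, `residual_mean`, `residual_sd`,
#'   `skewness`, `kurtosis_excess`, `abs_residual_bins` (proportions,
#'   summing to 1) and `qq` (data frame `theoretical`, `sample`).
#' @export
residual_diagnostics <- function(observed, predicted, cuts = c(0.1, 0.2, 0.3)) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  n <- length(observed)
  if (n < 8L) stop("need at least 8 samples for residual diagnostics", call. = FALSE)
  r <- observed - predicted
  abs_bins <- table(cut(abs(r), breaks = c(-Inf, cuts, Inf),
                        labels = c(sprintf("lt_%g", cuts[1L]),
                                   sprintf("%g_to_%g", cuts[-length(cuts)], cuts[-1L]),
                                   sprintf("gt_%g", cuts[length(cuts)]))))
  srt <- sort(r)
  pp <- stats::ppoints(n)
  list(
    residuals = r,
    residual_mean = mean(r),
    residual_sd = stats::sd(r),
    skewness = sample_skewness(r),
    kurtosis_excess = sample_excess_kurtosis(r),
    abs_residual_bins = as.list(abs_bins / n),
    qq = data.frame(
      theoretical = stats::qnorm(pp, mean(r), stats::sd(r)),
      sample = srt
    )
  )
}

#' Residuals stratified by measured biomass
#'
#' Groups residuals either by the quartiles of the measured biomass
#' (`scheme = "quartiles"`, groups Q1-Q4) or by fixed biomass intervals
#' (`scheme = "fixed_intervals"`, default breaks 1.0 / 1.3 / 1.6 kg m^-2
#' giving low, medium-low, medium-high and high). Intervals are
#' lower-closed, upper-open except the unbounded tails.
#'
#' @param observed,predicted Numeric vectors (n >= 8).
#' @param scheme `"quartiles"` or `"fixed_intervals"`.
#' @param breaks Interval cut points for the fixed scheme.
#' @return Data frame with one row per group: `group`, `n`,
#'   `mean_residual`, `median_residual`, `mae`. Empty groups are reported
#'   with `n = 0` and `NA` summaries.
#' @export
stratified_errors <- function(observed, predicted,
                              scheme = c("quartiles", "fixed_intervals"),
                              breaks = c(1.0, 1.3, 1.6)) {
  scheme <- match.arg(scheme)
  if (length(observed) < 8L) stop("need at least 8 samples", call. = FALSE)
  r <- observed - predicted
  if (scheme == "quartiles") {
    q <- pct_linear(observed, c(0.25, 0.5, 0.75))
    grp <- cut(observed, breaks = c(-Inf, q, Inf), right = FALSE,
               labels = c("Q1", "Q2", "Q3", "Q4"))
    # cut() with right = FALSE puts each quartile boundary in the upper group
    levels_all <- c("Q1", "Q2", "Q3", "Q4")
  } else {
    labels <- c(sprintf("lt_%g", breaks[1L]),
                sprintf("%g_to_%g", breaks[-length(breaks)], breaks[-1L]),
                sprintf("ge_%g", breaks[length(breaks)]))
    grp <- cut(observed, breaks = c(-Inf, breaks, Inf), right = FALSE,
               labels = labels)
    levels_all <- labels
  }
  out <- do.call(rbind, lapply(levels_all, function(g) {
    sel <- grp == g
    data.frame(
      group = g, n = sum(sel),
      mean_residual = if (any(sel)) mean(r[sel]) else NA_real_,
      median_residual = if (any(sel)) stats::median(r[sel]) else NA_real_,
      mae = if (any(sel)) mean(abs(r[sel])) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Full evaluation report
#'
#' Bundles [regression_metrics()], [residual_diagnostics()] and both
#' [stratified_errors()] schemes, plus the slope and intercept of the
#' predicted-versus-observed regression line.
#'
#' @param observed,predicted Numeric vectors (n >= 8).
#' @return List of class `evaluation_report`.
#' @export
evaluation_report <- function(observed, predicted) {
  m <- regression_metrics(observed, predicted)
  line <- stats::coef(stats::lm(predicted ~ observed))
  structure(
    c(m, residual_diagnostics(observed, predicted),
      list(quartile_group_residuals = stratified_errors(observed, predicted, "quartiles"),
           interval_errors = stratified_errors(observed, predicted, "fixed_intervals"),
           regression_line = list(intercept = unname(line[1L]),
                                  slope = unname(line[2L])),
           n = length(observed))),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d\n", x$n))
  cat(sprintf("  R2 %.3f, RMSE %.3f, MAE %.3f kg/m^2\n", x$R2, x$RMSE, x$MAE))
  cat(sprintf("  residual mean %.3f, sd %.3f, skewness %.3f, excess kurtosis %.3f\n",
              x$residual_mean, x$residual_sd, x$skewness, x$kurtosis_excess))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$qq <- NULL
  out$residuals <- as.numeric(out$residuals)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Per-stage test metrics
#'
#' Evaluates a fitted model on the test rows of each growth stage. Stages
#' with fewer than `min_n` rows are flagged low-confidence; stages with
#' fewer than 2 rows (or constant biomass) get `NA` metrics.
#'
#' @param model A fitted `biomass_ensemble`.
#' @param test Test rows with `stage` and `biomass` columns.
#' @param min_n Minimum stage size for a confident estimate (default 5).
#' @return Data frame with one row per stage: `stage`, `n`, `R2`, `RMSE`,
#'   `MAE`, `low_confidence`.
#' @export
stage_metrics <- function(model, test, min_n = 5L) {
  if (!"stage" %in% names(test)) stop("test rows need a `stage` column", call. = FALSE)
  pred <- predict(model, test)
  out <- do.call(rbind, lapply(unique(test$stage), function(s) {
    sel <- test$stage == s
    ok <- sum(sel) >= 2L && stats::var(test$biomass[sel]) > 0
    m <- if (ok) regression_metrics(test$biomass[sel], pred[sel])
         else list(R2 = NA_real_, RMSE = NA_real_, MAE = NA_real_)
    data.frame(stage = s, n = sum(sel), R2 = m$R2, RMSE = m$RMSE, MAE = m$MAE,
               low_confidence = sum(sel) < min_n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Feature-combination comparison
#'
#' Trains and evaluates the ensemble with spectral-only, LiDAR-only and
#' fused feature sets under one identical train/test split and seed.
#' Spectral-only uses the spectral provenance columns; LiDAR-only the
#' structural columns (with the absence indicator); fused all feature
#' columns including interactions, geometry and treatment.
#'
#' @param table A `feature_table` with measured biomass.
#' @param train_fraction,seed Split specification.
#' @param config An [ensemble_config()].
#' @param n_folds Folds for the weight search.
#' @param combos Named list mapping combination name to feature columns;
#'   the default builds the three standard sets from provenance.
#' @return List with `results` (data frame: combination, n_features, R2,
#'   RMSE, MAE), `models`, and the `split`.
#' @export
feature_combination_study <- function(table, train_fraction = 0.85, seed = 1L,
                                      config = ensemble_config(), n_folds = 10L,
                                      combos = NULL) {
  if (is.null(combos)) {
    combos <- list(
      spectral_only = feature_columns(table, "spectral"),
      lidar_only = feature_columns(table, c("structural", "indicator")),
      fused = feature_columns(table)
    )
  }
  if (any(lengths(combos) == 0L)) {
    stop("empty feature combination: ",
         paste(names(combos)[lengths(combos) == 0L], collapse = ", "), call. = FALSE)
  }
  parts <- split_train_test(table, train_fraction = train_fraction, seed = seed)
  models <- list()
  rows <- list()
  for (nm in names(combos)) {
    fit <- biomass_ensemble(parts$train, features = combos[[nm]],
                            config = config, n_folds = n_folds, seed = seed)
    pred <- predict(fit, parts$test)
    m <- regression_metrics(parts$test$biomass, pred)
    models[[nm]] <- fit
    rows[[nm]] <- data.frame(combination = nm, n_features = length(combos[[nm]]),
                             R2 = m$R2, RMSE = m$RMSE, MAE = m$MAE,
                             stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, models = models, split = parts)
}

#' Top-k feature ablation
#'
#' Retrains and evaluates the ensemble using the top `k` features of an
#' importance ranking, for each `k`, under one fixed split and seed.
#' `k = Inf` (reported as `"all"`) uses every ranked feature. A `k`
#' exceeding the feature count is clamped with a warning.
#'
#' @param table A `feature_table` with measured biomass.
#' @param ranking An `importance_ranking`.
#' @param ks Feature counts (default `c(5, 8, 10, 12, 15, Inf)`).
#' @param train_fraction,seed Split specification.
#' @param config An [ensemble_config()].
#' @param n_folds Folds for the weight search.
#' @return Data frame: `k` (label), `n_features`, `R2`, `RMSE`, `MAE`.
#' @export
topk_ablation <- function(table, ranking, ks = c(5, 8, 10, 12, 15, Inf),
                          train_fraction = 0.85, seed = 1L,
                          config = ensemble_config(), n_folds = 10L) {
  parts <- split_train_test(table, train_fraction = train_fraction, seed = seed)
  p <- nrow(ranking)
  rows <- lapply(ks, function(k) {
    kk <- if (is.finite(k)) as.integer(k) else p
    if (kk > p) {
      warning("k = ", kk, " exceeds the ", p, "-feature ranking; clamped")
      kk <- p
    }
    feats <- ranking$feature[seq_len(kk)]
    fit <- biomass_ensemble(parts$train, features = feats, config = config,
                            n_folds = n_folds, seed = seed)
    m <- regression_metrics(parts$test$biomass, predict(fit, parts$test))
    data.frame(k = if (is.finite(k)) as.character(k) else "all",
               n_features = kk, R2 = m$R2, RMSE = m$RMSE, MAE = m$MAE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-stage impurity importance
#'
#' Recomputes the impurity-based feature importance on the rows of each
#' growth stage and normalizes per stage, for cross-stage comparison of
#' feature contributions. Stages with fewer than `min_rows` rows are
#' reported absent (`NA` column).
#'
#' @param table A `feature_table` with `stage` and measured biomass.
#' @param forest_config Overrides for [impurity_forest()].
#' @param min_rows Minimum rows per stage (default 20).
#' @param seed Integer seed.
#' @return Matrix features x stages of normalized importance (columns sum
#'   to 1 where computed).
#' @export
stagewise_importance <- function(table, forest_config = list(), min_rows = 20L,
                                 seed = 1L) {
  stages <- unique(table$stage)
  if (length(stages) < 2L) stop("need at least 2 stages", call. = FALSE)
  cols <- feature_columns(table)
  out <- matrix(NA_real_, length(cols), length(stages),
                dimnames = list(cols, stages))
  for (s in stages) {
    sub <- table[table$stage == s & !is.na(table$biomass), , drop = FALSE]
    if (nrow(sub) < min_rows) next
    rank_s <- impurity_importance(sub, forest_config = forest_config, seed = seed)
    out[rank_s$feature, s] <- rank_s$importance
  }
  out
}
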