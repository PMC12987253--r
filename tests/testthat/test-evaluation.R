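# Metrics, residual diagnostics, stratified errors and the study designs.

test_that("regression metrics match hand arithmetic and boundary cases", {
  obs <- c(1, 2, 3)
  m <- regression_metrics(obs, c(1.1, 1.9, 3.2))
  expect_equal(m$RMSE, sqrt(0.06 / 3))
  expect_equal(m$MAE, 0.4 / 3)
  expect_equal(m$R2, 1 - 0.06 / 2)

  perfect <- regression_metrics(obs, obs)
  expect_equal(perfect$R2, 1)
  expect_equal(perfect$RMSE, 0)
  expect_equal(perfect$MAE, 0)

  expect_equal(regression_metrics(obs, rep(mean(obs), 3))$R2, 0)
  expect_error(regression_metrics(obs, c(1, 2)), "lengths")
  expect_error(regression_metrics(c(2, 2, 2), obs), "constant")
})

test_that("residual diagnostics report the documented statistics and bins", {
  obs <- seq(0.5, 2, length.out = 10)
  sym <- c(-0.05, 0.05, -0.02, 0.02, -0.08, 0.08, -0.03, 0.03, -0.01, 0.01)
  d <- residual_diagnostics(obs, obs - sym)
  expect_equal(d$skewness, 0, tolerance = 1e-12)
  expect_equal(d$residual_mean, 0, tolerance = 1e-12)
  # every |residual| < 0.1: all mass in the first bin
  expect_equal(d$abs_residual_bins$lt_0.1, 1)
  expect_equal(sum(unlist(d$abs_residual_bins)), 1)

  # bin proportions match direct counting at the 0.1/0.2/0.3 cuts
  res <- c(0.05, -0.15, 0.25, -0.35, 0.12, 0.02, -0.28, 0.31)
  d2 <- residual_diagnostics(seq_along(res), seq_along(res) - res)
  expect_equal(d2$abs_residual_bins$lt_0.1, 2 / 8)
  expect_equal(d2$abs_residual_bins$`0.1_to_0.2`, 2 / 8)
  expect_equal(d2$abs_residual_bins$`0.2_to_0.3`, 2 / 8)
  expect_equal(d2$abs_residual_bins$gt_0.3, 2 / 8)

  # large standard normal sample: moments within 3 standard errors
  set.seed(77)
  z <- rnorm(1e5)
  d3 <- residual_diagnostics(z, rep(0, 1e5))
  expect_lt(abs(d3$skewness), 3 * sqrt(6 / 1e5))
  expect_lt(abs(d3$kurtosis_excess), 3 * sqrt(24 / 1e5))
  expect_equal(nrow(d3$qq), 1e5)

  expect_error(residual_diagnostics(1:5, 1:5), "at least 8")
})

test_that("stratified errors expose shrinkage bias with the documented conventions", {
  set.seed(15)
  y <- runif(200, 0.5, 2.0)
  # unbiased predictions: group medians near zero
  unb <- stratified_errors(y, y + rnorm(200, 0, 0.05), scheme = "quartiles")
  expect_true(all(abs(unb$median_residual) < 0.05))
  expect_equal(sum(unb$n), 200L)

  # shrinkage toward the mean: top quartile positive, bottom negative
  shrunk <- mean(y) + 0.5 * (y - mean(y))
  st <- stratified_errors(y, shrunk, scheme = "quartiles")
  expect_gt(st$mean_residual[st$group == "Q4"], 0)
  expect_lt(st$mean_residual[st$group == "Q1"], 0)

  # 8 samples -> exactly 2 per quartile
  y8 <- 1:8
  st8 <- stratified_errors(y8, y8 + 0.1, scheme = "quartiles")
  expect_equal(st8$n, rep(2L, 4L))

  # fixed intervals use the lower-closed convention and report empty groups
  yi <- c(0.5, 0.9, 1.0, 1.2, 1.3, 1.5, 1.8, 2.0)
  sti <- stratified_errors(yi, yi, scheme = "fixed_intervals")
  expect_equal(sti$group, c("lt_1", "1_to_1.3", "1.3_to_1.6", "ge_1.6"))
  expect_equal(sti$n, c(2L, 2L, 2L, 2L))  # 1.0 and 1.3 go to the upper bins
  ylow <- c(0.5, 0.7, 0.9, 1.0, 1.1, 1.2, 1.3, 1.5)
  none_high <- stratified_errors(ylow, ylow, "fixed_intervals")
  expect_equal(none_high$n[4L], 0L)
  expect_true(is.na(none_high$mae[4L]))
})

test_that("evaluation reports bundle metrics, line fit and stratifications", {
  set.seed(16)
  y <- runif(50, 0.5, 2)
  p <- y + rnorm(50, 0, 0.1)
  rep <- evaluation_report(y, p)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(rep$n, 50L)
  expect_equal(rep$R2, regression_metrics(y, p)$R2)
  line <- coef(lm(p ~ y))
  expect_equal(rep$regression_line$slope, unname(line[2L]))
  expect_equal(nrow(rep$quartile_group_residuals), 4L)
  dir <- withr::local_tempdir()
  write_report(rep, file.path(dir, "rep.json"))
  j <- jsonlite::read_json(file.path(dir, "rep.json"), simplifyVector = TRUE)
  expect_equal(j$R2, rep$R2, tolerance = 1e-12)
})

test_that("stage metrics equal global metrics for one stage and flag degenerate ones", {
  tab <- planted_table(n = 90L)
  tab$stage <- "bud"
  parts <- split_train_test(tab, seed = 2L)
  fit <- biomass_ensemble(parts$train, config = light_config(), n_folds = 4L, seed = 2L)
  sm <- stage_metrics(fit, parts$test)
  glob <- regression_metrics(parts$test$biomass, predict(fit, parts$test))
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$R2, glob$R2)
  expect_equal(sm$MAE, glob$MAE)

  # a stage with one sample is flagged with absent R2
  one <- parts$test
  one$stage[1L] <- "lonely"
  sm2 <- stage_metrics(fit, one)
  expect_true(is.na(sm2$R2[sm2$stage == "lonely"]))
  expect_true(sm2$low_confidence[sm2$stage == "lonely"])
})

test_that("per-stage accuracy tracks the stage noise level", {
  set.seed(21)
  n <- 240L
  x <- runif(n)
  stage <- rep(c("clean", "noisy"), each = n / 2)
  noise <- ifelse(stage == "clean", 0.05, 0.6)
  df <- data.frame(id = as.character(seq_len(n)), x = x, stage = stage,
                   biomass = x + rnorm(n, 0, noise))
  prov <- c(x = "spectral")
  tab <- canopyfuse:::as_feature_table(df, prov)
  parts <- split_train_test(tab, seed = 3L)
  fit <- biomass_ensemble(parts$train, features = "x", config = light_config(),
                          n_folds = 4L, seed = 3L)
  sm <- stage_metrics(fit, parts$test)
  expect_gt(sm$R2[sm$stage == "clean"], sm$R2[sm$stage == "noisy"])
})

test_that("feature-combination studies respect identical splits and destroyed signals", {
  tab <- planted_table(n = 120L)
  prov <- attr(tab, "provenance")
  prov[c("x1", "x2")] <- "spectral"
  prov[c("x3", "x4")] <- "structural"
  prov[c("x5", "x6")] <- "geometry"
  attr(tab, "provenance") <- prov

  # identical feature sets under two labels give identical metrics
  study <- feature_combination_study(
    tab, seed = 5L, config = light_config(), n_folds = 4L,
    combos = list(a = c("x1", "x2"), b = c("x1", "x2")))
  expect_equal(study$results$R2[1L], study$results$R2[2L])
  expect_equal(study$results$RMSE[1L], study$results$RMSE[2L])

  # shuffling the spectral columns against the target destroys that combo
  wreck <- tab
  wreck$x1 <- canopyfuse:::with_seed(9L, sample(wreck$x1))
  wreck$x2 <- canopyfuse:::with_seed(10L, sample(wreck$x2))
  study2 <- feature_combination_study(
    wreck, seed = 5L, config = light_config(), n_folds = 4L,
    combos = list(spectral_only = c("x1", "x2"),
                  structural_only = c("x3", "x4")))
  expect_lt(study2$results$R2[study2$results$combination == "spectral_only"], 0.3)

  expect_error(feature_combination_study(tab, combos = list(a = character(0))),
               "empty")
})

test_that("top-k ablation plateaus at the planted signal size", {
  tab <- planted_table(n = 140L, p = 8L, noise = 0.05)
  rk <- impurity_importance(tab, forest_config = list(n_trees = 60L, mtry = 8L),
                            seed = 7L)
  expect_equal(sort(rk$feature[1:3]), c("x1", "x2", "x3"))
  ab <- topk_ablation(tab, rk, ks = c(1, 3, 5, Inf), seed = 7L,
                      config = light_config(), n_folds = 4L)
  expect_equal(ab$k, c("1", "3", "5", "all"))
  r2 <- ab$R2
  # k = 1 on a three-factor signal is strictly below the full set
  expect_lt(r2[1L], r2[4L])
  # plateau once the signal features are in
  expect_gt(r2[2L], r2[4L] - 0.05)

  # k = all reproduces a direct fit with the same features, split and seed
  parts <- split_train_test(tab, seed = 7L)
  direct <- biomass_ensemble(parts$train, features = rk$feature,
                             config = light_config(), n_folds = 10L, seed = 7L)
  m <- regression_metrics(parts$test$biomass, predict(direct, parts$test))
  ab_all <- topk_ablation(tab, rk, ks = Inf, seed = 7L, config = light_config(),
                          n_folds = 10L)
  expect_equal(ab_all$R2, m$R2, tolerance = 1e-12)

  expect_warning(topk_ablation(tab, rk, ks = 99, seed = 7L,
                               config = light_config(), n_folds = 4L),
                 "clamped")
})

test_that("stagewise importance finds stage-specific drivers and normalizes per stage", {
  set.seed(30)
  n <- 120L
  stage <- rep(c("early", "late"), each = n / 2)
  xs <- runif(n)   # drives biomass only in the early stage
  xh <- runif(n)   # drives biomass only in the late stage
  y <- ifelse(stage == "early", xs, xh) + rnorm(n, 0, 0.05)
  df <- data.frame(id = as.character(seq_len(n)), stage = stage,
                   spectral_like = xs, structural_like = xh, biomass = y)
  tab <- canopyfuse:::as_feature_table(
    df, c(spectral_like = "spectral", structural_like = "structural"))
  M <- stagewise_importance(tab, forest_config = list(n_trees = 60L, mtry = 2L),
                            seed = 8L)
  expect_equal(dim(M), c(2L, 2L))
  expect_equal(colSums(M), c(early = 1, late = 1), tolerance = 1e-12)
  expect_gt(M["spectral_like", "early"], M["structural_like", "early"])
  expect_gt(M["structural_like", "late"], M["spectral_like", "late"])

  # identical stages give identical rankings at a fixed seed
  df2 <- df
  df2$stage <- rep(c("a", "b"), times = n / 2)
  df2$biomass <- xs + rnorm(n, 0, 0.05)
  tab2 <- canopyfuse:::as_feature_table(
    df2, c(spectral_like = "spectral", structural_like = "structural"))
  M2 <- stagewise_importance(tab2, forest_config = list(n_trees = 40L, mtry = 2L),
                             seed = 8L)
  expect_equal(which.max(M2[, "a"]), which.max(M2[, "b"]))
})
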