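# canopyfuse

Quadrat-scale prediction of alfalfa aboveground biomass (kg m⁻²) from fused
UAV multispectral reflectance and LiDAR canopy structure.

Forage biomass is measured destructively — clip a 1 m × 1 m quadrat, dry it,
weigh it — which cannot scale or repeat. UAV surveys observe the same
quadrats non-destructively through two complementary channels:
five-band reflectance (Blue, Green, Red, RedEdge, NIR) tracking pigment and
canopy density, and LiDAR point clouds resolving three-dimensional canopy
structure. Each channel alone has a known failure mode — vegetation indices
saturate once the canopy closes (high biomass gets underestimated), while
structural metrics relate to dry mass only indirectly. `canopyfuse`
implements the full fusion pipeline for agronomists and remote-sensing
researchers who want both channels in one tested model.

## What the package does

* **Registration** — bivariate polynomial transform fitted by least squares
  on control-point pairs, with RMSE-driven iterative refinement and
  lowest-adequate-order selection.
* **Spectral features per quadrat ROI** — inward buffer (5–10 cm), masking
  cascade (NDVI < 0.20, NIR < 0.05, any band > 0.95, 1st/99th percentile
  exclusion), band statistics and percentiles, histogram-shape features, and
  vegetation index means

  NDVI = (NIR−Red)/(NIR+Red), NDRE = (NIR−RedEdge)/(NIR+RedEdge),
  GNDVI = (NIR−Green)/(NIR+Green), MSR = (NIR/Red−1)/(NIR/Red+1),
  EVI = 2.5(NIR−Red)/(NIR+6Red−7.5Blue+1), SAVI = 1.5(NIR−Red)/(NIR+Red+L).
* **Structural features** — k-NN statistical outlier removal, progressive
  morphological ground filtering, height-above-ground normalization
  (vegetation band 0.05–3.0 m), then H-statistics and percentiles, density,
  coverage above 0.3/1.0 m, vertical stratum proportions, echo intensity
  statistics and convex hull area.
* **Feature selection** — impurity (variance-reduction) importance
  FIⱼ = (1/M) Σₘ Σ_{t:v(t)=j} ΔI(t,j), with
  ΔI(t,j) = I(t) − (N_L/N_t) I(t_L) − (N_R/N_t) I(t_R) and I(t) the node
  variance, normalized and cut at 95% cumulative contribution.
* **Model** — robust-scaled features into a weighted soft-voting ensemble
  ŷ = w_RF ŷ_RF + w_ET ŷ_ET + w_HGB ŷ_HGB of random forest, extremely
  randomized trees and histogram gradient boosting; weights found on the
  simplex from 10-fold out-of-fold predictions on the training set only.
* **Evaluation** — R²/RMSE/MAE, residual distribution diagnostics,
  quartile and biomass-interval stratified errors, per-stage metrics,
  spectral-only vs LiDAR-only vs fused comparison, top-k ablation,
  per-stage importance dynamics.
* **Synthetic scenes** — a generator with known per-quadrat biomass,
  saturating cover and height responses, contamination and a fertilizer
  covariate, so the whole pipeline is testable end to end without field
  data.

See the methods vignette (`vignettes/biomass-fusion-methods.Rmd`) for the
model assumptions, parameter defaults and numerical conventions.

## Worked example

```r
library(canopyfuse)

scene <- generate_scene(scene_config(n_quadrats = 60, seed = 1))
tab   <- extract_features(scene$raster, scene$cloud, scene$quadrats)

ranking <- impurity_importance(tab, seed = 1)
keep    <- select_by_cumulative_importance(ranking, 0.95)

parts <- split_train_test(tab, seed = 1)
fit   <- biomass_ensemble(parts$train, features = keep, seed = 1)
summary(fit)
evaluation_report(parts$test$biomass, predict(fit, parts$test))
```

Output:

```
<synthetic_scene> 60 quadrats, 36843 points, raster 320 x 320 px
<feature_table> 60 quadrats x 188 features (geometry 3, indicator 1,
  interaction 66, spectral 91, structural 26, treatment 1)

Weighted soft-voting ensemble (RF + ET + HGB)
  training rows: 51, features: 110
  out-of-fold R2 per learner:
    rf   0.933 (weight 0.00)
    et   0.942 (weight 0.95)
    hgb  0.898 (weight 0.05)
  out-of-fold R2, weighted ensemble: 0.942

<evaluation_report> n = 9
  R2 0.805, RMSE 0.118, MAE 0.090 kg/m^2
  residual mean -0.020, sd 0.123, skewness -0.818, excess kurtosis -0.638
```

The selection kept 110 of 188 features (top of the ranking: `NIR_min`,
`NIR_p70`, `NIR_p50`, `NDRE`, `NDVI` — spectral levels and red-edge indices
dominate, as expected when canopy cover drives the signal). The held-out R²
of 0.805 means the fused model explains ~80% of the biomass variance in the
nine test quadrats; the RMSE of 0.118 kg m⁻² is the typical prediction
error against clipped dry weight.

A full configured run (generate → extract → rank → select → train →
evaluate, every artifact persisted) is one call:

```r
run_pipeline(list(synthetic = list(n_quadrats = 60),
                  seed = 1, out_dir = "run1"))
```

or, from a shell, via the thin CLI wrapper
`inst/cli/canopyfuse.R all --config run.yaml --seed 1`.

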