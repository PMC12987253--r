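Package: canopyfuse
Title: Multimodal Canopy Data Fusion for Forage Biomass Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quadrat-scale prediction of alfalfa aboveground biomass from
    co-registered UAV multispectral reflectance rasters and LiDAR point
    clouds. Implements polynomial control-point registration with RMSE-based
    order selection, a pixel masking cascade (NDVI, NIR, saturation and
    percentile filters) with per-band spectral statistics, histogram-shape
    features and vegetation indices, progressive morphological ground
    filtering with height-above-ground normalization and canopy structure
    metrics, impurity-based (variance-reduction) feature importance with
    cumulative-contribution selection, and a weighted soft-voting ensemble of
    random forest, extremely randomized trees and histogram gradient
    boosting. Includes a synthetic-scene generator with known ground-truth
    biomass so the full pipeline is testable end to end, plus a diagnostic
    evaluation suite (residual distribution, quartile and biomass-interval
    stratification, feature-combination and top-k ablation studies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
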