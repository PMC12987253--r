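# Synthetic paired scenes: a five-band reflectance raster, a LiDAR-like
# point cloud and quadrat ROIs with known generative biomass, emulating the
# acquisition regime of a UAV multispectral + LiDAR survey over fertilized
# alfalfa plots. The generator is the package's test bed: every downstream
# stage is exercised against its known ground truth.
#
# Generative model per quadrat:
#   biomass b        ~ Normal(1.266, 0.413) truncated to `biomass_range`,
#                      shifted by a small fertilizer effect
#   canopy cover     c(b) = 1 - exp(-k b), k = log(20)/2 so c(2.0) = 0.95
#   effective cover  c* = c(b) + quadrat-level Gaussian noise (sd 0.03)
#   reflectance      linear soil/vegetation mixture in c* per band
#                    (Red decreases, NIR increases, saturating in b through c)
#   height scale     h(b) = h_max b / (b + b_half) times lognormal noise
#   point heights    Beta(2, 3) scaled by the height scale
#   veg-return share c* times lognormal penetration noise
#   echo intensity   mean increasing in c*, lognormal quadrat noise
# The quadrat-level noise terms represent canopy properties that real
# reflectance and point clouds confound with biomass (background, lodging,
# penetration), and are what keeps the spectral channel dominant but
# saturating and the structural channel informative but indirect.

#' Scene configuration
#'
#' Validated parameter record for [generate_scene()]. Defaults reproduce the
#' emulated survey: 1 m quadrats on a regular grid with one quadrat-side
#' spacing, 0.05 m ground sampling distance, 175 points per square meter,
#' biomass between 0.3 and 2.2 kg m^-2.
#'
#' @param n_quadrats Number of quadrats (default 270).
#' @param quadrat_side Quadrat side length (m, default 1).
#' @param pixel_size Raster pixel size (m, default 0.05).
#' @param biomass_range Biomass interval (kg m^-2), within `(0, 3]`.
#' @param noise_sd_reflectance Per-pixel reflectance noise sd (default 0.01).
#' @param noise_sd_height Per-point elevation noise sd (m, default 0.03).
#' @param shadow_fraction,saturation_fraction Per-pixel contamination
#'   probabilities inside quadrats (defaults 0.02, 0.01).
#' @param outlier_count_per_quadrat High outlier points injected above each
#'   canopy (default 2).
#' @param points_per_m2 Point density (default 175).
#' @param stage_label Growth-stage labels, assigned to quadrats in
#'   contiguous blocks (acquisition batches).
#' @param fertilizer_levels Fertilizer levels as fractions of the
#'   conventional rate, cycled across quadrats.
#' @param cover_k Cover response rate; default `log(20)/2` so that
#'   `c(2.0) = 0.95`.
#' @param h_max,b_half Height response asymptote (m) and half-saturation
#'   biomass (kg m^-2).
#' @param cover_noise_sd Quadrat-level effective-cover noise sd (default 0.03).
#' @param height_lognoise_sd,penetration_lognoise_sd,intensity_lognoise_sd
#'   Quadrat-level lognormal noise sds for height scale, vegetation-return
#'   share and intensity mean.
#' @param fertilizer_effect Biomass shift (kg m^-2) per unit fertilizer rate
#'   deviation from conventional (default 0.2).
#' @param extent Optional fixed scene extent `c(width, height)` in m; errors
#'   if the quadrat grid cannot fit.
#' @param seed Integer seed; identical (config, seed) pairs reproduce
#'   byte-identical scenes.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(n_quadrats = 270L, quadrat_side = 1.0, pixel_size = 0.05,
                         biomass_range = c(0.3, 2.2),
                         noise_sd_reflectance = 0.01, noise_sd_height = 0.03,
                         shadow_fraction = 0.02, saturation_fraction = 0.01,
                         outlier_count_per_quadrat = 2L, points_per_m2 = 175,
                         stage_label = c("regrowth", "branching", "bud", "flowering"),
                         fertilizer_levels = c(0, 0.5, 0.75, 1, 1.25, 1.5),
                         cover_k = log(20) / 2, h_max = 1.0, b_half = 0.8,
                         cover_noise_sd = 0.02, height_lognoise_sd = 0.04,
                         penetration_lognoise_sd = 0.3, intensity_lognoise_sd = 0.2,
                         fertilizer_effect = 0.2, extent = NULL, seed = 1L) {
  stopifnot(n_quadrats >= 1, quadrat_side > 0)
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  if (points_per_m2 <= 0) stop("`points_per_m2` must be positive", call. = FALSE)
  fr <- c(shadow_fraction, saturation_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (length(biomass_range) != 2L || biomass_range[1L] <= 0 ||
      biomass_range[2L] > 3 || diff(biomass_range) <= 0) {
    stop("`biomass_range` must be an increasing interval within (0, 3]", call. = FALSE)
  }
  if (!all(fertilizer_levels %in% c(0, 0.5, 0.75, 1, 1.25, 1.5))) {
    stop("fertilizer levels must be fractions of the conventional rate in {0, 0.5, 0.75, 1, 1.25, 1.5}",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %d quadrats, %.2g m px, %g pts/m^2, biomass [%.2g, %.2g] kg/m^2, seed %d\n",
              x$n_quadrats, x$pixel_size, x$points_per_m2,
              x$biomass_range[1L], x$biomass_range[2L], x$seed))
  invisible(x)
}

# Reflectance endmembers (unitless). Bare soil has NDVI 0.12 so fully
# uncovered pixels fall to the cascade's non-vegetation threshold.
SOIL_REFLECTANCE <- c(Blue = 0.10, Green = 0.15, Red = 0.22, RedEdge = 0.26, NIR = 0.28)
VEG_REFLECTANCE <- c(Blue = 0.04, Green = 0.08, Red = 0.05, RedEdge = 0.30, NIR = 0.50)

# Deterministic mean reflectance for effective cover c: a matrix with one
# row per cover value and one column per band.
cover_reflectance <- function(cover) {
  out <- vapply(CANOPYFUSE_BANDS,
                function(b) cover * VEG_REFLECTANCE[[b]] + (1 - cover) * SOIL_REFLECTANCE[[b]],
                numeric(length(cover)))
  if (length(cover) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(NULL, CANOPYFUSE_BANDS))
  out
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, pmin(plo, phi), pmax(plo, phi)), mean, sd)
}

#' Generate a synthetic scene
#'
#' Draws per-quadrat biomass and latent canopy parameters, renders the
#' five-band raster, samples the point cloud (ground and vegetation returns,
#' echo intensity), injects the configured contamination (shadow pixels with
#' NIR forced below 0.05, saturated pixels with NIR forced above 0.95, high
#' outlier points above the canopy) and returns everything with the
#' generative ground truth attached.
#'
#' @param config A [scene_config()].
#' @return An object of class `synthetic_scene`: list with `raster`
#'   (`reflectance_raster`), `cloud` (`canopy_cloud`), `quadrats`
#'   (`quadrat_rois`), `true_params` (data frame of generative coefficients
#'   per quadrat) and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  n <- cfg$n_quadrats
  side <- cfg$quadrat_side
  tile <- 2 * side  # one quadrat-side spacing between quadrats
  ncol_t <- ceiling(sqrt(n))
  nrow_t <- ceiling(n / ncol_t)
  W <- ncol_t * tile
  H <- nrow_t * tile
  if (!is.null(cfg$extent)) {
    if (cfg$extent[1L] < W || cfg$extent[2L] < H) {
      stop(sprintf("quadrat grid (%g x %g m) cannot fit the requested extent (%g x %g m)",
                   W, H, cfg$extent[1L], cfg$extent[2L]), call. = FALSE)
    }
    W <- cfg$extent[1L]; H <- cfg$extent[2L]
  }
  ps <- cfg$pixel_size
  ncol_px <- as.integer(round(W / ps))
  nrow_px <- as.integer(round(H / ps))

  # --- latent quadrat parameters -------------------------------------------
  qi <- seq_len(n)
  tile_col <- (qi - 1L) %% ncol_t
  tile_row <- (qi - 1L) %/% ncol_t
  x0 <- tile_col * tile + (tile - side) / 2
  y0 <- tile_row * tile + (tile - side) / 2   # distance from the top edge
  fert <- rep_len(cfg$fertilizer_levels, n)
  # stages come in contiguous blocks, like acquisition batches
  stage <- rep(cfg$stage_label,
               each = ceiling(n / length(cfg$stage_label)))[seq_len(n)]
  b_mean <- 1.266 + cfg$fertilizer_effect * (fert - 1)
  biomass <- rtruncnorm(n, b_mean, 0.413, cfg$biomass_range[1L], cfg$biomass_range[2L])
  cover <- 1 - exp(-cfg$cover_k * biomass)
  cover_eff <- pmin(pmax(cover + stats::rnorm(n, 0, cfg$cover_noise_sd), 0.01), 0.995)
  h_scale <- cfg$h_max * biomass / (biomass + cfg$b_half) *
    exp(stats::rnorm(n, 0, cfg$height_lognoise_sd))
  penetration <- pmin(pmax(cover_eff * exp(stats::rnorm(n, 0, cfg$penetration_lognoise_sd)),
                           0.02), 0.98)
  intensity_mean <- 800 * (0.3 + 0.5 * cover_eff) *
    exp(stats::rnorm(n, 0, cfg$intensity_lognoise_sd))

  # --- raster ---------------------------------------------------------------
  bands <- lapply(SOIL_REFLECTANCE, function(v) matrix(v, nrow_px, ncol_px))
  cx <- (seq_len(ncol_px) - 0.5) * ps       # pixel center x
  cy <- (seq_len(nrow_px) - 0.5) * ps       # pixel center distance from top
  for (q in qi) {
    cols <- which(cx > x0[q] & cx < x0[q] + side)
    rows <- which(cy > y0[q] & cy < y0[q] + side)
    mu <- cover_reflectance(cover_eff[q])
    for (b in CANOPYFUSE_BANDS) bands[[b]][rows, cols] <- mu[, b]
  }
  if (cfg$noise_sd_reflectance > 0) {
    for (b in CANOPYFUSE_BANDS) {
      bands[[b]] <- pmin(pmax(
        bands[[b]] + matrix(stats::rnorm(nrow_px * ncol_px, 0, cfg$noise_sd_reflectance),
                            nrow_px, ncol_px), 0.001), 0.949)
    }
  }
  # contamination inside quadrat footprints
  if (cfg$shadow_fraction > 0 || cfg$saturation_fraction > 0) {
    for (q in qi) {
      cols <- which(cx > x0[q] & cx < x0[q] + side)
      rows <- which(cy > y0[q] & cy < y0[q] + side)
      cells <- as.matrix(expand.grid(row = rows, col = cols))
      u <- stats::runif(nrow(cells))
      shadow <- u < cfg$shadow_fraction
      sat <- !shadow & u < cfg$shadow_fraction + cfg$saturation_fraction
      if (any(shadow)) bands$NIR[cells[shadow, , drop = FALSE]] <- 0.03
      if (any(sat)) bands$NIR[cells[sat, , drop = FALSE]] <- 0.97
    }
  }
  raster <- reflectance_raster(bands, origin = c(0, H), pixel_size = ps)

  # --- point cloud ----------------------------------------------------------
  pts <- vector("list", n + 1L)
  for (q in qi) {
    n_q <- round(cfg$points_per_m2 * side^2)
    n_veg <- round(n_q * penetration[q])
    n_gnd <- n_q - n_veg
    vx <- stats::runif(n_veg, x0[q], x0[q] + side)
    vy <- stats::runif(n_veg, y0[q], y0[q] + side)
    height <- pmin(stats::rbeta(n_veg, 2, 3) * h_scale[q], 3.0)
    vz <- height + stats::rnorm(n_veg, 0, cfg$noise_sd_height)
    vi <- pmax(stats::rnorm(n_veg, intensity_mean[q], 80), 0)
    gx <- stats::runif(n_gnd, x0[q], x0[q] + side)
    gy <- stats::runif(n_gnd, y0[q], y0[q] + side)
    gz <- stats::rnorm(n_gnd, 0, cfg$noise_sd_height)
    gi <- pmax(stats::rnorm(n_gnd, 150, 50), 0)
    ox <- oy <- oz <- oi <- numeric(0)
    if (cfg$outlier_count_per_quadrat > 0) {
      n_out <- cfg$outlier_count_per_quadrat
      ox <- stats::runif(n_out, x0[q], x0[q] + side)
      oy <- stats::runif(n_out, y0[q], y0[q] + side)
      oz <- stats::runif(n_out, 4, 8)
      oi <- pmax(stats::rnorm(n_out, 100, 30), 0)
    }
    pts[[q]] <- data.frame(
      x = c(vx, gx, ox), y_top = c(vy, gy, oy), z = c(vz, gz, oz),
      intensity = c(vi, gi, oi)
    )
  }
  # ground-only points between the quadrats
  n_bg <- round(cfg$points_per_m2 * (W * H - n * side^2))
  bgx <- stats::runif(n_bg, 0, W)
  bgy <- stats::runif(n_bg, 0, H)
  in_quadrat <- rep(FALSE, n_bg)
  for (q in qi) {
    in_quadrat <- in_quadrat | (bgx > x0[q] & bgx < x0[q] + side &
                                bgy > y0[q] & bgy < y0[q] + side)
  }
  pts[[n + 1L]] <- data.frame(
    x = bgx[!in_quadrat], y_top = bgy[!in_quadrat],
    z = stats::rnorm(sum(!in_quadrat), 0, cfg$noise_sd_height),
    intensity = pmax(stats::rnorm(sum(!in_quadrat), 150, 50), 0)
  )
  all_pts <- do.call(rbind, pts)
  cloud <- canopy_cloud(all_pts$x, H - all_pts$y_top, all_pts$z,
                        intensity = all_pts$intensity)

  # --- quadrat ROIs ---------------------------------------------------------
  polys <- lapply(qi, function(q) {
    # convert the top-based offsets to map y (origin at bottom)
    rbind(c(x0[q], H - y0[q]),
          c(x0[q] + side, H - y0[q]),
          c(x0[q] + side, H - (y0[q] + side)),
          c(x0[q], H - (y0[q] + side)))
  })
  rois <- quadrat_rois(
    id = sprintf("Q%03d", qi), polygons = polys, biomass = biomass,
    stage = stage, fertilizer_level = fert, batch_date = "synthetic"
  )
  truth <- data.frame(
    id = rois$id, biomass = biomass, cover = cover, cover_eff = cover_eff,
    height_scale = h_scale, penetration = penetration,
    intensity_mean = intensity_mean, fertilizer_level = fert, stage = stage,
    stringsAsFactors = FALSE
  )
  structure(list(raster = raster, cloud = cloud, quadrats = rois,
                 true_params = truth, config = cfg),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d quadrats, %d points, raster %d x %d px\n",
              nrow(x$quadrats), nrow(x$cloud),
              nrow(x$raster$bands[[1L]]), ncol(x$raster$bands[[1L]])))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Writes `raster.tif` (+ `.json` sidecar), `cloud.csv`, `quadrats.geojson`
#' and `ground_truth.csv` under `dir`.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(scene$raster, file.path(dir, "raster.tif"))
  write_cloud(scene$cloud, file.path(dir, "cloud.csv"))
  write_rois(scene$quadrats, file.path(dir, "quadrats.geojson"))
  utils::write.csv(scene$true_params, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
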