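#' Configuration for a synthetic coastal landscape
#'
#' Defines the grid, the geographic window, the coastline roughness and the
#' per-predictor noise levels used by [make_domain()] and [make_predictors()].
#' Defaults emulate a temperate north-west Pacific coastal shelf: benthic
#' mean temperature spanning 2-28 degC along the latitudinal gradient, depth
#' increasing offshore toward 3000 m over a wide, gently sloping shelf
#' (nearshore cells a few tens of metres deep, as on the Bohai/Yellow Sea
#' shelf), salinity 29-35, so that physiological
#' constants such as an optimum of 15-18 degC, an upper limit of 26 degC and
#' a 200 m depth limit are meaningful on the synthetic layers.
#'
#' @param n_rows,n_cols Grid size (>= 10 each). Rows run south to north.
#' @param lat_range,lon_range Geographic window, degrees (min, max).
#' @param coast_complexity Coastline roughness >= 0, in grid columns of
#'   excursion; 0 gives a straight north-south coastline.
#' @param land_frac Approximate fraction of columns occupied by land.
#' @param noise_sd Named numeric vector of additive noise SDs (predictor
#'   units) for the gradient-driven layers; names among `temp_mean`, `depth`.
#' @param temp_limits,trange_limits,sal_limits,curr_limits Value ranges of
#'   the corresponding layers (degC, degC, psu, m/s).
#' @param depth_max_m Maximum depth reached far offshore (m).
#' @param depth_halfsat_km Distance-to-shore (km) at which depth reaches half
#'   of `depth_max_m` (hyperbolic bathymetry profile).
#' @param kernel_sd Gaussian smoothing kernel SD (cells) for random fields.
#' @param seed Integer seed; every stochastic step is reproducible from it.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 60, n_cols = 80,
                             lat_range = c(22, 52), lon_range = c(118, 158),
                             coast_complexity = 3, land_frac = 0.3,
                             noise_sd = c(temp_mean = 0.6, depth = 20),
                             temp_limits = c(2, 28), trange_limits = c(4, 16),
                             sal_limits = c(29, 35), curr_limits = c(0.02, 1.2),
                             depth_max_m = 3000, depth_halfsat_km = 2000,
                             kernel_sd = 4, seed = 1L) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              lat_range = lat_range, lon_range = lon_range,
              coast_complexity = coast_complexity, land_frac = land_frac,
              noise_sd = noise_sd, temp_limits = temp_limits,
              trange_limits = trange_limits, sal_limits = sal_limits,
              curr_limits = curr_limits, depth_max_m = depth_max_m,
              depth_halfsat_km = depth_halfsat_km, kernel_sd = kernel_sd,
              seed = as.integer(seed))
  validate_landscape_config(cfg)
  structure(cfg, class = "landscape_config")
}

validate_landscape_config <- function(cfg) {
  if (cfg$n_rows < 10 || cfg$n_cols < 10)
    stopf("n_rows and n_cols must be >= 10 (got %d x %d)", cfg$n_rows, cfg$n_cols)
  if (diff(cfg$lat_range) <= 0) stopf("lat_range is degenerate")
  if (diff(cfg$lon_range) <= 0) stopf("lon_range is degenerate")
  if (cfg$coast_complexity < 0) stopf("coast_complexity must be >= 0")
  if (any(cfg$noise_sd < 0)) stopf("noise_sd entries must be >= 0")
  if (cfg$land_frac <= 0 || cfg$land_frac >= 1)
    stopf("land_frac must lie strictly between 0 and 1")
  invisible(cfg)
}

#' Build the landscape domain (grid + sea/land mask)
#'
#' Land occupies the western margin up to a meandering coastline; sea lies to
#' the east. The coastline column varies smoothly with latitude, with
#' excursion controlled by `coast_complexity` (0 = straight line).
#'
#' @param cfg A [landscape_config()].
#' @return An [env_stack()] skeleton (no layers yet) whose `meta` records the
#'   config; deterministic for a fixed `cfg$seed`.
#' @export
make_domain <- function(cfg) {
  validate_landscape_config(cfg)
  lon <- seq(cfg$lon_range[1], cfg$lon_range[2], length.out = cfg$n_cols + 1)
  lon <- (lon[-1] + lon[-length(lon)]) / 2
  lat <- seq(cfg$lat_range[1], cfg$lat_range[2], length.out = cfg$n_rows + 1)
  lat <- (lat[-1] + lat[-length(lat)]) / 2

  base_col <- cfg$land_frac * cfg$n_cols
  if (cfg$coast_complexity > 0) {
    set.seed(derive_seed(cfg$seed, 11L))
    wiggle <- smooth_matrix(matrix(rnorm(cfg$n_rows), ncol = 1), cfg$kernel_sd)
    wiggle <- wiggle / max(stats::sd(wiggle), 1e-12) * cfg$coast_complexity
  } else {
    wiggle <- matrix(0, cfg$n_rows, 1)
  }
  coast_col <- pmin(pmax(round(base_col + wiggle[, 1]), 1L), cfg$n_cols - 1L)
  sea <- matrix(FALSE, cfg$n_rows, cfg$n_cols)
  for (i in seq_len(cfg$n_rows)) sea[i, (coast_col[i] + 1L):cfg$n_cols] <- TRUE

  if (!any(sea)) stopf("degenerate grid: all land (check land_frac)")
  if (all(sea)) stopf("degenerate grid: all sea (check land_frac)")
  env_stack(lon, lat, sea, meta = list(config = unclass(cfg),
                                       coast_col = coast_col))
}

#' Populate the six synthetic predictor layers
#'
#' Adds `temp_mean` (annual mean benthic temperature, degC; decreasing with
#' latitude plus smooth noise), `depth` (m; increasing hyperbolically with
#' distance to shore), `dist_shore` (km; great-circle distance to the nearest
#' land cell center), and smoothed random fields for `temp_range` (degC),
#' `salinity` (psu) and `current` (m/s) within their configured limits. Land
#' cells are `NA` everywhere.
#'
#' @param domain An [env_stack()] from [make_domain()].
#' @param cfg The same [landscape_config()].
#' @return The completed [env_stack()].
#' @export
make_predictors <- function(domain, cfg) {
  validate_landscape_config(cfg)
  nr <- length(domain$lat); nc <- length(domain$lon)
  sea <- domain$sea

  # distance to shore (km), nearest land cell center
  land_idx <- which(!sea, arr.ind = TRUE)
  sea_idx <- which(sea, arr.ind = TRUE)
  land_pts <- cbind(domain$lon[land_idx[, 2]], domain$lat[land_idx[, 1]])
  sea_pts <- cbind(domain$lon[sea_idx[, 2]], domain$lat[sea_idx[, 1]])
  dist_shore <- matrix(NA_real_, nr, nc)
  chunk <- 2000L
  for (s in seq(1L, nrow(sea_pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(sea_pts))
    d <- gc_cross_dist_km(sea_pts[s:e, , drop = FALSE], land_pts)
    dist_shore[sea_idx[s:e, , drop = FALSE]] <- apply(d, 1L, min)
  }

  set.seed(derive_seed(cfg$seed, 22L))
  nsd <- function(nm) unname(cfg$noise_sd[nm] %||% 0)
  sd_t <- if (!is.na(nsd("temp_mean"))) nsd("temp_mean") else 0
  sd_d <- if (!is.na(nsd("depth"))) nsd("depth") else 0

  # latitudinal thermal gradient: warm south, cold north
  lat01 <- (domain$lat - min(domain$lat)) / diff(range(domain$lat))
  temp_base <- cfg$temp_limits[2] - lat01 * diff(cfg$temp_limits)
  temp_mean <- matrix(temp_base, nr, nc)
  if (sd_t > 0) temp_mean <- temp_mean + sd_t * random_field(nr, nc, cfg$kernel_sd)

  depth <- cfg$depth_max_m * dist_shore / (dist_shore + cfg$depth_halfsat_km)
  if (sd_d > 0) {
    depth <- depth + sd_d * random_field(nr, nc, cfg$kernel_sd)
    depth <- pmax(depth, 1)
  }

  temp_range <- rescale_range(random_field(nr, nc, cfg$kernel_sd),
                              cfg$trange_limits[1], cfg$trange_limits[2])
  salinity <- rescale_range(random_field(nr, nc, cfg$kernel_sd),
                            cfg$sal_limits[1], cfg$sal_limits[2])
  current <- rescale_range(random_field(nr, nc, cfg$kernel_sd),
                           cfg$curr_limits[1], cfg$curr_limits[2])

  env_stack(domain$lon, domain$lat, sea,
            layers = list(depth = depth, dist_shore = dist_shore,
                          temp_mean = temp_mean, temp_range = temp_range,
                          salinity = salinity, current = current),
            meta = domain$meta)
}

#' Simulate a synthetic landscape in one call
#'
#' Convenience wrapper: [make_domain()] then [make_predictors()].
#' @param cfg A [landscape_config()].
#' @return An [env_stack()] with the six predictor layers.
#' @export
simulate_landscape <- function(cfg) make_predictors(make_domain(cfg), cfg)

# ---------------------------------------------------------------------------

#' Suitability map container
#'
#' Per-cell presence probability on the landscape grid; `NA` outside the
#' domain (land, or outside a projection mask).
#'
#' @param values Numeric matrix of probabilities conforming to the grid.
#' @param env The [env_stack()] providing grid geometry.
#' @param meta Optional metadata list.
#' @return Object of class `suit_map`.
#' @export
suit_map <- function(values, env, meta = list()) {
  stopifnot(identical(dim(values), dim(env$sea)))
  structure(list(values = values, lon = env$lon, lat = env$lat,
                 sea = env$sea, meta = meta), class = "suit_map")
}

#' @export
print.suit_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<suit_map> %d x %d, %d cells with values in [%.3f, %.3f]\n",
              length(x$lat), length(x$lon), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' True suitability from a known plateau response
#'
#' Forward-evaluates the plateau model (no sampling) on every sea cell:
#' `p = plogis(beta0 + sum_j f_j(x_j))` with `f_j` the trapezoidal penalty
#' of [plateau_response()], using predictor values normalized through
#' `transform`.
#'
#' @param env An [env_stack()] with the predictors named by `truth`.
#' @param truth A [plateau_params()] object (the generating "teacher").
#' @param transform A normalization transform from [normalize_predictors()];
#'   `NULL` normalizes by the min-max over all sea cells.
#' @return A [suit_map()].
#' @export
true_suitability <- function(env, truth, transform = NULL) {
  truth <- as_plateau_params(truth)
  missing <- setdiff(truth$params$predictor, names(env$layers))
  if (length(missing))
    stopf("truth references missing layer(s): %s", paste(missing, collapse = ", "))
  if (is.null(transform)) transform <- global_transform(env, truth$params$predictor)
  cells <- stack_cells(env, complete_only = TRUE)
  X <- normalize_values(cells[truth$params$predictor], transform)
  p <- presence_probability(X, truth)
  vals <- matrix(NA_real_, length(env$lat), length(env$lon))
  vals[cbind(cells$row, cells$col)] <- p
  suit_map(vals, env, meta = list(source = "true_response"))
}

#' Sample presence records from a suitability surface
#'
#' Draws up to `n_target` distinct presence cells with probability
#' proportional to `suitability x bias^bias_strength`, where the bias surface
#' is a smoothed log-normal random field (a continuous dial from unbiased
#' sampling at `bias_strength = 0` to strongly uneven survey effort). An
#' optional `region` mask restricts the sampled area, emulating geographically
#' truncated survey effort (e.g. no sampling of the warm range edge).
#'
#' @param suit A [suit_map()].
#' @param n_target Number of presences wanted (>= 1).
#' @param bias_strength Exponent >= 0 applied to the bias field.
#' @param seed Integer seed.
#' @param region Optional logical matrix; sampling restricted to its `TRUE`
#'   cells.
#' @return An [occurrence_set()] of presences at cell centers (possibly empty
#'   when the suitability surface is identically zero).
#' @export
sample_occurrences <- function(suit, n_target, bias_strength = 0, seed = 1L,
                               region = NULL) {
  if (n_target < 1) stopf("n_target must be >= 1")
  keep <- suit$sea & !is.na(suit$values)
  if (!is.null(region)) keep <- keep & region
  idx <- which(keep, arr.ind = TRUE)
  w <- suit$values[idx]
  set.seed(derive_seed(seed, 33L))
  if (bias_strength > 0) {
    bias <- exp(random_field(length(suit$lat), length(suit$lon), 4))
    w <- w * bias[idx]^bias_strength
  }
  pos <- which(w > 0)
  if (!length(pos)) {
    return(occurrence_set(data.frame(lon = numeric(0), lat = numeric(0),
                                     label = character(0)),
                          meta = list(seed = seed, n_target = n_target)))
  }
  if (length(pos) < n_target)
    stopf("cannot place %d presences: only %d cells have positive sampling weight",
          n_target, length(pos))
  pick <- sample(pos, n_target, replace = FALSE, prob = w[pos])
  occurrence_set(data.frame(lon = suit$lon[idx[pick, 2]],
                            lat = suit$lat[idx[pick, 1]],
                            label = "presence"),
                 meta = list(seed = seed, n_target = n_target,
                             bias_strength = bias_strength))
}

#' Warmed future predictor stack
#'
#' Shifts the temperature layers by spatially smooth warming fields with
#' exact sea-cell means `delta_temp` and `delta_range`; depth, distance to
#' shore, salinity and current velocity are copied unchanged (the
#' geographic predictors are constant across time by construction).
#'
#' @param env Present-day [env_stack()].
#' @param delta_temp Mean warming of `temp_mean` (degC).
#' @param delta_range Mean change of `temp_range` (degC).
#' @param seed Integer seed.
#' @param warming_sd SD (degC) of the smooth spatial heterogeneity around
#'   each delta; 0 gives a spatially uniform shift.
#' @return An [env_stack()] on the same grid and mask.
#' @export
make_future <- function(env, delta_temp, delta_range = 0, seed = 1L,
                        warming_sd = 0.3) {
  nr <- length(env$lat); nc <- length(env$lon)
  set.seed(derive_seed(seed, 44L))
  shift_field <- function(delta) {
    if (warming_sd == 0) return(matrix(delta, nr, nc))
    f <- warming_sd * random_field(nr, nc, 4)
    f - mean(f[env$sea]) + delta # exact sea-mean = delta
  }
  layers <- env$layers
  layers$temp_mean <- layers$temp_mean + shift_field(delta_temp)
  layers$temp_range <- layers$temp_range + shift_field(delta_range)
  meta <- env$meta
  meta$future <- list(delta_temp = delta_temp, delta_range = delta_range,
                      warming_sd = warming_sd, seed = seed)
  env_stack(env$lon, env$lat, env$sea, layers, meta = meta)
}
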