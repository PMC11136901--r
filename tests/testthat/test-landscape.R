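test_that("zero-roughness coastline is a straight north-south line", {
  cfg <- landscape_config(n_rows = 20, n_cols = 25, coast_complexity = 0, seed = 1)
  dom <- make_domain(cfg)
  coast <- apply(dom$sea, 1, function(r) min(which(r)))
  expect_length(unique(coast), 1L)
  # everything east of the coastline is sea, everything west is land
  expect_true(all(dom$sea[, coast[1]:ncol(dom$sea)]))
  expect_false(any(dom$sea[, seq_len(coast[1] - 1)]))
})

test_that("domain generation is seed-deterministic and partitions the grid", {
  cfg <- landscape_config(n_rows = 50, n_cols = 80, seed = 7)
  d1 <- make_domain(cfg)
  d2 <- make_domain(cfg)
  expect_identical(d1$sea, d2$sea)
  expect_equal(sum(d1$sea) + sum(!d1$sea), 50 * 80)
  expect_true(any(d1$sea) && any(!d1$sea))
})

test_that("degenerate land fractions are rejected with the parameter named", {
  expect_error(landscape_config(land_frac = 0), "land_frac")
  expect_error(landscape_config(n_rows = 5), "n_rows")
  expect_error(landscape_config(lat_range = c(30, 30)), "lat_range")
  expect_error(landscape_config(noise_sd = c(temp_mean = -1)), "noise_sd")
})

test_that("noiseless temperature decreases with latitude along every meridian", {
  cfg <- landscape_config(n_rows = 20, n_cols = 25, seed = 3,
                          noise_sd = c(temp_mean = 0, depth = 0))
  env <- simulate_landscape(cfg)
  # rows are ordered south -> north, so temperature must be non-increasing
  for (j in seq_along(env$lon)) {
    v <- env$layers$temp_mean[, j]
    v <- v[!is.na(v)]
    if (length(v) > 1) expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("distance to shore respects the adjacency bound and bathymetry is monotone", {
  cfg <- landscape_config(n_rows = 20, n_cols = 30, coast_complexity = 0, seed = 2,
                          noise_sd = c(temp_mean = 0, depth = 0))
  env <- simulate_landscape(cfg)
  coast <- min(which(env$sea[1, ]))
  # one cell diagonal in km at the widest (southernmost) row
  dx <- gc_dist_km(c(env$lon[1], env$lat[1]), c(env$lon[2], env$lat[1]))
  dy <- gc_dist_km(c(env$lon[1], env$lat[1]), c(env$lon[1], env$lat[2]))
  diag_km <- sqrt(dx^2 + dy^2)
  first_sea <- env$layers$dist_shore[, coast]     # cells adjacent to land
  expect_true(all(first_sea <= diag_km + 1e-9))
  # depth grows moving offshore (10 cells out, noiseless)
  expect_true(all(env$layers$depth[, coast] < env$layers$depth[, coast + 10]))
})

test_that("all layers share the grid, mask and no-data convention", {
  env <- tiny_landscape()$env
  for (nm in names(env$layers)) {
    expect_identical(dim(env$layers[[nm]]), dim(env$sea))
    expect_identical(is.na(env$layers[[nm]]), !env$sea)
  }
})

test_that("true suitability is the exact forward plateau evaluation", {
  L <- tiny_landscape()
  # on-plateau everywhere -> probability = plogis(intercept)
  flat_truth <- plateau_params(1.2, data.frame(
    predictor = names(L$env$layers), c1 = -1e6, c2 = 1e6, b1 = 1, b2 = 1))
  s <- true_suitability(L$env, flat_truth, L$transform)
  expect_equal(unique(round(s$values[!is.na(s$values)], 12)), round(plogis(1.2), 12))
  # zero slopes -> spatially constant regardless of edges
  zero_truth <- plateau_params(0.3, data.frame(
    predictor = names(L$env$layers), c1 = 0.4, c2 = 0.6, b1 = 0, b2 = 0))
  s0 <- true_suitability(L$env, zero_truth, L$transform)
  expect_equal(unique(round(s0$values[!is.na(s0$values)], 12)), round(plogis(0.3), 12))
  # far beyond the descending edge -> probability ~ 0
  hot <- plateau_params(2, data.frame(predictor = "temp_mean",
                                      c1 = -100, c2 = -50, b1 = 0, b2 = 50))
  sh <- true_suitability(L$env, hot, L$transform)
  expect_lt(max(sh$values, na.rm = TRUE), 1e-6)
  # missing layer named in the truth errors
  bad <- plateau_params(0, data.frame(predictor = "no_such_layer",
                                      c1 = 0, c2 = 1, b1 = 1, b2 = 1))
  expect_error(true_suitability(L$env, bad, L$transform), "no_such_layer")
})

test_that("occurrence sampling: empty surface, determinism, achievable-count error", {
  L <- tiny_landscape()
  zero <- suit_map(ifelse(L$env$sea, 0, NA), L$env)
  expect_equal(nrow(sample_occurrences(zero, 10, seed = 1)), 0L)
  o1 <- sample_occurrences(L$suit, 40, seed = 8)
  o2 <- sample_occurrences(L$suit, 40, seed = 8)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
  expect_false(identical(as.data.frame(o1),
                         as.data.frame(sample_occurrences(L$suit, 40, seed = 9))))
  # at most one presence per cell
  expect_false(any(duplicated(o1[c("lon", "lat")])))
  # restrict to a tiny region with few positive cells -> informative error
  few <- L$suit
  few$values[] <- 0
  pos <- which(L$env$sea, arr.ind = TRUE)[1:5, , drop = FALSE]
  few$values[pos] <- 0.5
  expect_error(sample_occurrences(few, 10, seed = 1), "only 5")
})

test_that("unbiased sampling over a constant surface is uniform (chi-square GOF)", {
  env <- flat_env(list(), n_rows = 12, n_cols = 15)
  suit <- suit_map(ifelse(env$sea, 0.5, NA), env)
  n_cells <- sum(env$sea)
  counts <- integer(n_cells)
  idx <- which(env$sea)
  for (s in 1:10) {
    occ <- sample_occurrences(suit, 60, bias_strength = 0, seed = 100 + s)
    rc <- plateauSDM:::snap_to_grid(env, occ$lon, occ$lat)
    hits <- (rc$col - 1L) * length(env$lat) + rc$row
    counts <- counts + tabulate(match(hits, idx), n_cells)
  }
  p <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / n_cells, n_cells)))$p.value
  expect_gt(p, 0.01)
})

test_that("presences oversample suitable cells", {
  L <- tiny_landscape()
  occ <- sample_occurrences(L$suit, 50, seed = 5)
  rc <- plateauSDM:::snap_to_grid(L$env, occ$lon, occ$lat)
  at_pres <- L$suit$values[cbind(rc$row, rc$col)]
  expect_gt(mean(at_pres), mean(L$suit$values, na.rm = TRUE))
})

test_that("future stacks shift temperature only, with the requested mean", {
  env <- tiny_landscape()$env
  # identity at zero deltas and zero heterogeneity
  f0 <- make_future(env, 0, 0, seed = 1, warming_sd = 0)
  expect_equal(f0$layers, env$layers)
  f2 <- make_future(env, 2, 0.5, seed = 1, warming_sd = 0.3)
  dT <- f2$layers$temp_mean - env$layers$temp_mean
  expect_equal(mean(dT[env$sea]), 2, tolerance = 1e-10)
  dR <- f2$layers$temp_range - env$layers$temp_range
  expect_equal(mean(dR[env$sea]), 0.5, tolerance = 1e-10)
  # the geographic predictors are bitwise unchanged
  expect_identical(f2$layers$depth, env$layers$depth)
  expect_identical(f2$layers$dist_shore, env$layers$dist_shore)
  expect_identical(f2$layers$salinity, env$layers$salinity)
})

test_that("stacks round-trip through ASCII grids with a JSON sidecar", {
  env <- tiny_landscape()$env
  prefix <- file.path(withr::local_tempdir(), "stack")
  write_env_stack(env, prefix)
  back <- read_env_stack(prefix)
  expect_identical(back$sea, env$sea)
  expect_equal(back$lon, env$lon, tolerance = 1e-9)
  expect_equal(back$lat, env$lat, tolerance = 1e-9)
  for (nm in names(env$layers))
    expect_equal(back$layers[[nm]], env$layers[[nm]], tolerance = 1e-8,
                 ignore_attr = TRUE)
})
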