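test_that("cleaning drops land records, deduplicates cells, and is idempotent", {
  env <- tiny_landscape()$env
  sea_idx <- which(env$sea, arr.ind = TRUE)
  land_idx <- which(!env$sea, arr.ind = TRUE)
  pt <- function(idx, i) c(env$lon[idx[i, 2]], env$lat[idx[i, 1]])
  p1 <- pt(sea_idx, 10); p2 <- pt(sea_idx, 50); pl <- pt(land_idx, 3)
  raw <- occurrence_set(data.frame(
    lon = c(p1[1], p1[1], p1[1], p2[1], pl[1]),
    lat = c(p1[2], p1[2], p1[2], p2[2], pl[2]),
    label = "presence"))
  out <- clean_records(raw, env)
  expect_equal(nrow(out), 2L)                      # 3 copies -> 1; land dropped
  log <- attr(out, "meta")$cleaning_log
  expect_equal(log$n_on_land, 1L)
  expect_equal(log$n_duplicate_cell, 2L)
  again <- clean_records(out, env)
  expect_equal(again[c("lon", "lat", "label")], out[c("lon", "lat", "label")])
  all_land <- occurrence_set(data.frame(lon = pl[1], lat = pl[2], label = "presence"))
  expect_error(clean_records(all_land, env), "removed")
})

test_that("thinning enforces the minimum pairwise distance", {
  # two points 5 km apart, 20-km threshold -> exactly one survives
  two <- occurrence_set(data.frame(lon = c(130, 130), lat = c(30, 30 + 5 / 111.2),
                                   label = "presence"))
  expect_equal(nrow(thin_records(two, 20, seed = 1)), 1L)
  # already-sparse set is untouched
  sparse <- occurrence_set(data.frame(lon = c(130, 135, 140), lat = c(30, 30, 30),
                                      label = "presence"))
  expect_equal(nrow(thin_records(sparse, 20, seed = 1)), 3L)
  # property: any input, any seed -> min pairwise distance >= threshold
  for (s in 1:4) {
    set.seed(s)
    occ <- occurrence_set(data.frame(lon = runif(60, 120, 124),
                                     lat = runif(60, 28, 32), label = "presence"))
    thinned <- thin_records(occ, 50, seed = s)
    d <- plateauSDM:::gc_dist_matrix_km(as.matrix(thinned[, c("lon", "lat")]))
    expect_gte(min(d[upper.tri(d)]), 50)
  }
  expect_error(thin_records(two, -1), "min_dist_km")
})

test_that("buffer areas match an independent distance check and nest by radius", {
  P <- prepared_landscape()
  env <- P$env
  a1000 <- P$a_small; a1500 <- buffer_area(P$occ, 1500, env); a2000 <- P$a_big
  # monotone nesting
  expect_true(all(a1000$mask <= a1500$mask))
  expect_true(all(a1500$mask <= a2000$mask))
  # every presence cell is inside its own buffer
  expect_true(all(a1000$mask[cbind(P$occ$row, P$occ$col)]))
  # oracle: membership iff great-circle distance to nearest presence <= r
  cells <- stack_cells(env)
  pick <- seq(1, nrow(cells), by = 7)
  pmat <- as.matrix(P$occ[, c("lon", "lat")])
  for (i in pick) {
    dmin <- min(gc_dist_km(cbind(cells$lon[i], cells$lat[i]), pmat))
    expect_identical(a1000$mask[cells$row[i], cells$col[i]], dmin <= 1000)
    expect_identical(a2000$mask[cells$row[i], cells$col[i]], dmin <= 2000)
  }
  expect_error(buffer_area(P$occ, -5, env), "radius")
})

test_that("pseudo-absences default to the presence count and avoid presence cells", {
  P <- prepared_landscape()
  pa <- draw_pseudo_absences(P$a_big, P$env, P$occ, seed = 31)
  expect_equal(nrow(pa), nrow(P$occ))
  expect_true(all(pa$label == "pseudo_absence"))
  pres_cells <- plateauSDM:::cell_index(P$env, P$occ$row, P$occ$col)
  pa_cells <- plateauSDM:::cell_index(P$env, pa$row, pa$col)
  expect_length(intersect(pa_cells, pres_cells), 0L)
  # inside the calibration area, on complete sea cells
  expect_true(all(P$a_big$mask[cbind(pa$row, pa$col)]))
  # different seeds give different sets
  pa2 <- draw_pseudo_absences(P$a_big, P$env, P$occ, seed = 32)
  expect_false(identical(sort(pa_cells),
                         sort(plateauSDM:::cell_index(P$env, pa2$row, pa2$col))))
  expect_error(draw_pseudo_absences(P$a_big, P$env, P$occ, n = 1e6), "eligible")
})

test_that("normalization maps extremes to 0/1, keeps constants mappable, never clips", {
  P <- prepared_landscape()
  tr <- P$transform_area
  cells <- stack_cells(P$env, mask = P$a_big$mask)
  for (nm in names(P$env$layers)) {
    v <- normalize_values(range(cells[[nm]], na.rm = TRUE), tr, nm)
    expect_equal(v, c(0, 1), tolerance = 1e-12)
  }
  # a physical constant maps through the stored affine transform
  i <- match("temp_mean", tr$layer)
  expect_equal(normalize_values(26, tr, "temp_mean"),
               (26 - tr$offset[i]) / tr$scale[i])
  expect_equal(normalize_values(normalize_values(26, tr, "temp_mean"), tr,
                                "temp_mean", invert = TRUE), 26)
  # warmed future values exceed 1 and are not clipped
  fut <- make_future(P$env, 5, 0, seed = 1, warming_sd = 0)
  fut_norm <- plateauSDM:::normalize_stack(fut, tr)
  expect_gt(max(fut_norm$layers$temp_mean, na.rm = TRUE), 1)
  # constant layer is rejected by name
  bad <- P$env
  bad$layers$salinity[bad$sea] <- 31
  expect_error(normalize_predictors(bad, P$a_big), "salinity")
})

test_that("bilinear regridding is exact for linear fields and propagates no-data", {
  src <- list(lon = seq(100.5, 111.5, by = 1), lat = seq(20.5, 29.5, by = 1))
  src$values <- outer(src$lat, src$lon, function(la, lo) 2 * lo + 3 * la)
  tlon <- seq(101.2, 110.7, by = 0.7); tlat <- seq(21.3, 28.9, by = 0.9)
  out <- regrid_bilinear(src, tlon, tlat)
  expect_equal(out, outer(tlat, tlon, function(la, lo) 2 * lo + 3 * la),
               tolerance = 1e-10)
  # constant field stays constant; identical grid is the identity
  srcc <- src; srcc$values[] <- 7
  expect_true(all(regrid_bilinear(srcc, tlon, tlat) == 7))
  expect_equal(regrid_bilinear(src, src$lon, src$lat), src$values,
               tolerance = 1e-10, ignore_attr = TRUE)
  # an NA corner poisons the four surrounding target cells
  srcna <- src; srcna$values[5, 6] <- NA
  outna <- regrid_bilinear(srcna, tlon, tlat)
  expect_true(anyNA(outna))
  expect_error(regrid_bilinear(src, tlon + 100, tlat), "overlap")
})

test_that("VIF matches the closed form from the empirical covariance", {
  set.seed(14)
  n_rows <- 40; n_cols <- 50; n <- n_rows * n_cols - 1
  Sigma <- matrix(c(1, 0.7, 0.3,
                    0.7, 1, 0.5,
                    0.3, 0.5, 1), 3)
  X <- MASS::mvrnorm(n, rep(0, 3), Sigma)
  to_layer <- function(v) {
    m <- matrix(NA_real_, n_rows, n_cols)
    m[-1] <- v  # skip the single land cell
    m
  }
  env <- flat_env(list(a = to_layer(X[, 1]), b = to_layer(X[, 2]),
                       c = to_layer(X[, 3])), n_rows, n_cols)
  got <- vif_check(env)
  S <- stats::cov(X)
  oracle <- diag(S) * diag(solve(S))
  expect_equal(got$vif, unname(oracle), tolerance = 1e-9)
  # and close to the population value implied by the known covariance
  pop <- diag(Sigma) * diag(solve(Sigma))
  expect_equal(got$vif, unname(pop), tolerance = 0.15)
  expect_true(all(got$pass))
  # orthogonal predictors -> VIF ~ 1; duplicated layer -> infinite VIF, fail
  env_dup <- flat_env(list(a = to_layer(X[, 1]), b = to_layer(X[, 1]),
                           c = to_layer(X[, 3])), n_rows, n_cols)
  vd <- suppressWarnings(vif_check(env_dup))  # lm warns on the perfect fit
  expect_true(any(is.infinite(vd$vif)))
  expect_false(all(vd$pass))
})

test_that("occurrences round-trip through CSV", {
  P <- prepared_landscape()
  path <- tempfile(fileext = ".csv")
  write_occurrences(P$all_occ, path)
  back <- read_occurrences(path)
  expect_equal(back$lon, P$all_occ$lon)
  expect_equal(back$label, P$all_occ$label)
})
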