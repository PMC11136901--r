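#' Min-max normalization of predictor layers
#'
#' Computes, per layer, the affine map `(x - offset) / scale` with `offset`
#' and `scale` the min and range over the cells of the given calibration
#' area (by study design, the *largest* buffer, so that every model variant
#' and every physiological constant shares one scale). Future layers pushed
#' through the same transform may exceed 1 and are deliberately not clipped.
#'
#' @param env An [env_stack()].
#' @param area A [calib_area()], or `NULL` to use all sea cells.
#' @return List with `env` (normalized copy of the stack) and `transform`
#'   (a `norm_transform`: data.frame of layer, offset, scale).
#' @export
normalize_predictors <- function(env, area = NULL) {
  mask <- if (is.null(area)) NULL else area$mask
  cells <- stack_cells(env, mask = mask)
  if (!nrow(cells)) stopf("calibration area contains no cells")
  tr <- global_transform_from_cells(cells, names(env$layers))
  out <- env
  for (nm in names(env$layers)) {
    i <- match(nm, tr$layer)
    out$layers[[nm]] <- (env$layers[[nm]] - tr$offset[i]) / tr$scale[i]
  }
  out$meta$normalized <- TRUE
  list(env = out, transform = tr)
}

global_transform_from_cells <- function(cells, layers) {
  off <- sc <- numeric(length(layers))
  for (i in seq_along(layers)) {
    v <- cells[[layers[i]]]
    r <- range(v, na.rm = TRUE)
    if (!is.finite(diff(r)) || diff(r) == 0)
      stopf("layer '%s' is constant over the normalization area", layers[i])
    off[i] <- r[1]; sc[i] <- diff(r)
  }
  structure(data.frame(layer = layers, offset = off, scale = sc),
            class = c("norm_transform", "data.frame"))
}

# transform from min-max over all sea cells (used for ground-truth forward
# evaluation on a synthetic stack)
global_transform <- function(env, layers = names(env$layers)) {
  global_transform_from_cells(stack_cells(env), layers)
}

#' Map physical values through a stored normalization transform
#'
#' @param x Numeric vector or data.frame (columns = layers) of physical
#'   values, e.g. the 26 degC thermal limit.
#' @param transform A `norm_transform` from [normalize_predictors()].
#' @param layer Layer name (when `x` is a vector).
#' @param invert Map normalized values back to physical units instead.
#' @return Normalized (or inverted) values, same shape as `x`.
#' @export
normalize_values <- function(x, transform, layer = NULL, invert = FALSE) {
  one <- function(v, nm) {
    i <- match(nm, transform$layer)
    if (is.na(i)) stopf("layer '%s' is not in the transform", nm)
    if (invert) v * transform$scale[i] + transform$offset[i]
    else (v - transform$offset[i]) / transform$scale[i]
  }
  if (is.data.frame(x)) {
    for (nm in names(x)) x[[nm]] <- one(x[[nm]], nm)
    x
  } else {
    if (is.null(layer)) stopf("layer must be given for vector input")
    one(x, layer)
  }
}

#' Bilinear regridding of a single raster layer
#'
#' Interpolates from the four enclosing source cell centers to each target
#' cell center; any `NA` corner makes the target cell `NA`, and targets
#' outside the source center hull are `NA`.
#'
#' @param src List with `lon`, `lat` (ascending center coordinates) and
#'   `values` (matrix `[lat, lon]`), e.g. one layer of an [env_stack()].
#' @param target_lon,target_lat Ascending center coordinates of the target
#'   grid.
#' @return Matrix `length(target_lat) x length(target_lon)`.
#' @export
regrid_bilinear <- function(src, target_lon, target_lat) {
  if (max(target_lon) < min(src$lon) || min(target_lon) > max(src$lon) ||
      max(target_lat) < min(src$lat) || min(target_lat) > max(src$lat))
    stopf("source and target grids do not overlap")
  v <- src$values
  ix <- findInterval(target_lon, src$lon)
  iy <- findInterval(target_lat, src$lat)
  out <- matrix(NA_real_, length(target_lat), length(target_lon))
  for (j in seq_along(target_lon)) {
    jx <- ix[j]
    if (jx < 1 || jx >= length(src$lon)) {
      # exactly on the last center counts as inside
      if (jx == length(src$lon) && target_lon[j] == src$lon[jx]) jx <- jx - 1L
      else next
    }
    tx <- (target_lon[j] - src$lon[jx]) / (src$lon[jx + 1] - src$lon[jx])
    for (i in seq_along(target_lat)) {
      jy <- iy[i]
      if (jy < 1 || jy >= length(src$lat)) {
        if (jy == length(src$lat) && target_lat[i] == src$lat[jy]) jy <- jy - 1L
        else next
      }
      ty <- (target_lat[i] - src$lat[jy]) / (src$lat[jy + 1] - src$lat[jy])
      q <- v[jy + 0:1, jx + 0:1]
      if (anyNA(q)) next
      out[i, j] <- (1 - ty) * ((1 - tx) * q[1, 1] + tx * q[1, 2]) +
                   ty * ((1 - tx) * q[2, 1] + tx * q[2, 2])
    }
  }
  out
}

#' Variance inflation factors over a calibration area
#'
#' Regresses each predictor on all others (ordinary least squares over the
#' area's complete cells) and reports `VIF = 1 / (1 - R^2)`; a perfectly
#' collinear predictor yields `Inf` and fails the check.
#'
#' @param env An [env_stack()] with >= 2 layers.
#' @param area A [calib_area()] or `NULL` for all sea cells.
#' @param threshold Failure threshold, default 10.
#' @return data.frame with `predictor`, `vif`, `pass`.
#' @export
vif_check <- function(env, area = NULL, threshold = 10) {
  layers <- names(env$layers)
  if (length(layers) < 2) stopf("need >= 2 predictors for VIF")
  cells <- stack_cells(env, mask = if (is.null(area)) NULL else area$mask,
                       complete_only = TRUE)
  if (nrow(cells) <= length(layers)) stopf("need more cells than predictors")
  X <- cells[layers]
  vif <- vapply(layers, function(nm) {
    fit <- lm(stats::reformulate(setdiff(layers, nm), response = nm), data = X)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = layers, vif = unname(vif),
             pass = unname(vif) < threshold, row.names = NULL)
}
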