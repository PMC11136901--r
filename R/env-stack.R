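#' Gridded environmental predictor stack
#'
#' An `env_stack` holds co-registered 2-D predictor layers on a regular
#' lon/lat (equirectangular) grid together with a sea/land mask. Matrices are
#' indexed `[row, col]` with row 1 the southernmost row; `lat`/`lon` give cell
#' *center* coordinates. Land cells carry `NA` in every layer.
#'
#' @param lon,lat Ascending cell-center coordinate vectors (degrees).
#' @param sea Logical matrix, `TRUE` for sea cells.
#' @param layers Named list of numeric matrices conforming to `sea`.
#' @param meta Optional list of provenance metadata.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(lon, lat, sea, layers = list(), meta = list()) {
  stopifnot(is.numeric(lon), is.numeric(lat), is.matrix(sea))
  if (nrow(sea) != length(lat) || ncol(sea) != length(lon))
    stopf("mask is %d x %d but lat/lon imply %d x %d",
          nrow(sea), ncol(sea), length(lat), length(lon))
  if (length(layers) && is.null(names(layers)))
    stopf("layers must be named")
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), dim(sea)))
      stopf("layer '%s' does not conform to the grid", nm)
    layers[[nm]][!sea] <- NA_real_
  }
  structure(list(lon = lon, lat = lat, sea = sea, layers = layers, meta = meta),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d x %d cells (%d sea, %d land)\n",
              length(x$lat), length(x$lon), sum(x$sea), sum(!x$sea)))
  cat(sprintf("  lon [%g, %g]  lat [%g, %g]\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  cat("  layers:", if (length(x$layers)) paste(names(x$layers), collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
dim.env_stack <- function(x) c(length(x$lat), length(x$lon))

layer_names <- function(env) names(env$layers)

# row/col -> linear index helpers -------------------------------------------

cell_index <- function(env, row, col) (col - 1L) * length(env$lat) + row

#' Table of sea cells with coordinates and predictor values
#'
#' @param env An [env_stack()].
#' @param mask Optional logical matrix restricting the cells returned
#'   (intersected with the sea mask).
#' @param complete_only Drop cells with any `NA` predictor value.
#' @return A data.frame with `row`, `col`, `lon`, `lat` and one column per
#'   layer.
#' @export
stack_cells <- function(env, mask = NULL, complete_only = FALSE) {
  keep <- env$sea
  if (!is.null(mask)) keep <- keep & mask
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1], col = idx[, 2],
                    lon = env$lon[idx[, 2]], lat = env$lat[idx[, 1]])
  for (nm in names(env$layers)) out[[nm]] <- env$layers[[nm]][idx]
  if (complete_only && length(env$layers))
    out <- out[complete.cases(out[names(env$layers)]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Snap lon/lat points to nearest cell centers; returns row/col (NA outside
# the grid extent by more than half a cell).
snap_to_grid <- function(env, lon, lat) {
  half_dx <- mean(diff(env$lon)) / 2
  half_dy <- mean(diff(env$lat)) / 2
  col <- vapply(lon, function(x) which.min(abs(env$lon - x)), integer(1))
  row <- vapply(lat, function(y) which.min(abs(env$lat - y)), integer(1))
  off <- abs(env$lon[col] - lon) > half_dx * (1 + 1e-8) |
         abs(env$lat[row] - lat) > half_dy * (1 + 1e-8)
  row[off] <- NA_integer_; col[off] <- NA_integer_
  data.frame(row = row, col = col)
}

# I/O -----------------------------------------------------------------------

#' Write / read an `env_stack` as ESRI ASCII grids plus a JSON sidecar
#'
#' Each layer goes to `<prefix>_<layer>.asc`; the sea mask to
#' `<prefix>_mask.asc` (1 sea / 0 land); layer names, units and metadata to
#' `<prefix>.json`. The ASCII grid convention (first data row = northernmost)
#' is handled on both paths.
#'
#' @param env An [env_stack()].
#' @param prefix Path prefix for the output files.
#' @return `write_env_stack` returns the sidecar path invisibly;
#'   `read_env_stack` returns an [env_stack()].
#' @export
write_env_stack <- function(env, prefix) {
  dx <- mean(diff(env$lon))
  for (nm in names(env$layers))
    write_ascii_grid(env$layers[[nm]], env, paste0(prefix, "_", nm, ".asc"))
  write_ascii_grid(ifelse(env$sea, 1, 0), env, paste0(prefix, "_mask.asc"))
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(layers = as.list(names(env$layers)), cellsize = dx,
         meta = env$meta),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_env_stack
#' @export
read_env_stack <- function(prefix) {
  sc <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mask <- read_ascii_grid(paste0(prefix, "_mask.asc"))
  sea <- mask$values > 0.5
  layers <- lapply(setNames(sc$layers, sc$layers), function(nm)
    read_ascii_grid(paste0(prefix, "_", nm, ".asc"))$values)
  env_stack(mask$lon, mask$lat, sea, layers, meta = as.list(sc$meta))
}

write_ascii_grid <- function(m, env, path) {
  dx <- mean(diff(env$lon))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", min(env$lon) - dx / 2),
    sprintf("yllcorner %.10g", min(env$lat) - dx / 2),
    sprintf("cellsize %.10g", dx),
    "NODATA_value -9999"), con)
  m[is.na(m)] <- -9999
  # ASCII grids run north -> south
  for (i in rev(seq_len(nrow(m))))
    writeLines(paste(formatC(m[i, ], format = "g", digits = 10), collapse = " "), con)
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  h <- setNames(as.numeric(vapply(hdr, `[`, "", 2)), vapply(hdr, `[`, "", 1))
  vals <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE] # back to south-first rows
  m[m == h[["nodata_value"]]] <- NA_real_
  lon <- h[["xllcorner"]] + (seq_len(h[["ncols"]]) - 0.5) * h[["cellsize"]]
  lat <- h[["yllcorner"]] + (seq_len(h[["nrows"]]) - 0.5) * h[["cellsize"]]
  list(lon = lon, lat = lat, values = m)
}
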