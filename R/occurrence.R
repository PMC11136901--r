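#' Point occurrence records
#'
#' A thin data.frame subclass holding lon/lat point records labelled
#' `presence` or `pseudo_absence`, with optional grid linkage columns
#' (`row`, `col`) added when records are snapped to an [env_stack()].
#'
#' @param records data.frame with columns `lon`, `lat`, `label`.
#' @param meta Provenance list (seeds, thresholds, cleaning log).
#' @return Object of class `occ_set` (and `data.frame`).
#' @export
occurrence_set <- function(records, meta = list()) {
  stopifnot(all(c("lon", "lat", "label") %in% names(records)))
  bad <- setdiff(unique(records$label), c("presence", "pseudo_absence"))
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  structure(as.data.frame(records), meta = meta,
            class = c("occ_set", "data.frame"))
}

occ_meta <- function(occ) attr(occ, "meta") %||% list()

with_meta <- function(occ, ...) {
  m <- occ_meta(occ)
  new <- list(...)
  m[names(new)] <- new
  attr(occ, "meta") <- m
  occ
}

presences <- function(occ) occ[occ$label == "presence", , drop = FALSE]

#' Read / write occurrences as CSV
#'
#' Plain `lon,lat,label` CSV, the on-disk exchange format for occurrence
#' records.
#' @param occ An [occurrence_set()].
#' @param path File path.
#' @return `read_occurrences` returns an [occurrence_set()].
#' @export
write_occurrences <- function(occ, path) {
  write.csv(occ[c("lon", "lat", "label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  occurrence_set(read.csv(path, stringsAsFactors = FALSE))
}

#' Clean occurrence records against a predictor stack
#'
#' Snaps records to the grid, drops records that fall on land (or outside the
#' grid), and keeps exactly one record per grid cell. The counts removed at
#' each step are recorded in the returned object's metadata (`cleaning_log`).
#'
#' @param raw An [occurrence_set()] (presences).
#' @param env An [env_stack()].
#' @return Cleaned [occurrence_set()] with `row`/`col` grid linkage.
#' @export
clean_records <- function(raw, env) {
  if (!nrow(raw)) stopf("no records to clean")
  rc <- snap_to_grid(env, raw$lon, raw$lat)
  off_grid <- is.na(rc$row)
  on_land <- !off_grid & !env$sea[cbind(rc$row, rc$col)]
  keep <- !off_grid & !on_land
  out <- cbind(raw[keep, c("lon", "lat", "label"), drop = FALSE],
               rc[keep, , drop = FALSE])
  dup <- duplicated(cell_index(env, out$row, out$col))
  out <- out[!dup, , drop = FALSE]
  if (!nrow(out)) stopf("all %d records removed during cleaning", nrow(raw))
  rownames(out) <- NULL
  log <- list(n_input = nrow(raw), n_off_grid = sum(off_grid),
              n_on_land = sum(on_land), n_duplicate_cell = sum(dup),
              n_retained = nrow(out))
  occurrence_set(out, meta = c(occ_meta(raw), list(cleaning_log = log)))
}

#' Spatially thin occurrence records
#'
#' Randomized max-retention thinning: repeatedly remove a uniformly chosen
#' record among those with the most neighbours closer than `min_dist_km`
#' (great-circle), until no pair violates the distance; repeated `n_rep`
#' times, returning the run that retains the most records (earlier run wins
#' ties).
#'
#' @param occ An [occurrence_set()].
#' @param min_dist_km Minimum pairwise distance to enforce (km), default 20.
#' @param n_rep Number of randomized repetitions.
#' @param seed Integer seed.
#' @return Thinned [occurrence_set()]; metadata records the parameters and
#'   the retained count.
#' @export
thin_records <- function(occ, min_dist_km = 20, n_rep = 10, seed = 1L) {
  if (min_dist_km <= 0) stopf("min_dist_km must be > 0")
  n <- nrow(occ)
  if (n <= 1) return(with_meta(occ, thin_km = min_dist_km))
  d <- gc_dist_matrix_km(as.matrix(occ[, c("lon", "lat")]))
  close <- d < min_dist_km
  diag(close) <- FALSE
  set.seed(derive_seed(seed, 55L))
  best <- NULL
  for (rep in seq_len(n_rep)) {
    alive <- rep(TRUE, n)
    cnt <- rowSums(close)
    while (any(cnt[alive] > 0)) {
      worst <- which(alive & cnt == max(cnt[alive]))
      drop <- if (length(worst) == 1) worst else sample(worst, 1)
      alive[drop] <- FALSE
      nb <- which(close[drop, ] & alive)
      cnt[nb] <- cnt[nb] - 1L
      cnt[drop] <- 0L
    }
    if (is.null(best) || sum(alive) > sum(best)) best <- alive
  }
  out <- occ[best, , drop = FALSE]
  rownames(out) <- NULL
  occurrence_set(out, meta = c(occ_meta(occ),
                               list(thin_km = min_dist_km, n_rep = n_rep,
                                    thin_seed = seed, n_retained = nrow(out))))
}

#' Buffered calibration area
#'
#' Marks every cell whose center lies within `radius_km` great-circle
#' distance of at least one presence record and inside the domain mask (the
#' EEZ-analogue). Areas built from the same presences nest monotonically in
#' the radius.
#'
#' @param presences An [occurrence_set()] with >= 1 presence.
#' @param radius_km Buffer radius (km), > 0; the study design uses
#'   1000 / 1500 / 2000 km.
#' @param env An [env_stack()] supplying grid geometry.
#' @param domain_mask Optional logical matrix further restricting the domain;
#'   defaults to the sea mask.
#' @return Object of class `calib_area`: list with `mask` (logical matrix),
#'   `buffer_km` and provenance.
#' @export
buffer_area <- function(presences, radius_km, env, domain_mask = NULL) {
  if (radius_km <= 0) stopf("radius_km must be > 0")
  pres <- presences[presences$label == "presence", , drop = FALSE]
  if (!nrow(pres)) stopf("no presence records to buffer around")
  dom <- env$sea
  if (!is.null(domain_mask)) dom <- dom & domain_mask
  idx <- which(dom, arr.ind = TRUE)
  pts <- cbind(env$lon[idx[, 2]], env$lat[idx[, 1]])
  mind <- rep(Inf, nrow(pts))
  chunk <- 4000L
  pmat <- as.matrix(pres[, c("lon", "lat")])
  for (s in seq(1L, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    d <- gc_cross_dist_km(pts[s:e, , drop = FALSE], pmat)
    mind[s:e] <- apply(d, 1L, min)
  }
  mask <- matrix(FALSE, length(env$lat), length(env$lon))
  mask[idx[mind <= radius_km, , drop = FALSE]] <- TRUE
  structure(list(mask = mask, buffer_km = radius_km,
                 n_presences = nrow(pres)),
            class = "calib_area")
}

#' @export
print.calib_area <- function(x, ...) {
  cat(sprintf("<calib_area> %g km buffer around %d presences: %d cells\n",
              x$buffer_km, x$n_presences, sum(x$mask)))
  invisible(x)
}

#' Draw pseudo-absences inside a calibration area
#'
#' Samples `n` cells uniformly without replacement from the calibration-area
#' cells that (a) have complete predictor data and (b) are not presence
#' cells; the drawn records are labelled `pseudo_absence` and placed at cell
#' centers. By study design `n` defaults to the number of presences.
#'
#' @param area A [calib_area()] from [buffer_area()].
#' @param env The [env_stack()].
#' @param exclude An [occurrence_set()] whose cells are excluded (the
#'   presences).
#' @param n Number of pseudo-absences; default `nrow(presences(exclude))`.
#' @param seed Integer seed.
#' @return An [occurrence_set()] of pseudo-absences.
#' @export
draw_pseudo_absences <- function(area, env, exclude, n = NULL, seed = 1L) {
  pres <- presences(exclude)
  if (is.null(n)) n <- nrow(pres)
  cells <- stack_cells(env, mask = area$mask, complete_only = TRUE)
  if (nrow(pres)) {
    rc <- if (all(c("row", "col") %in% names(pres))) pres[c("row", "col")]
          else snap_to_grid(env, pres$lon, pres$lat)
    cells <- cells[!(cell_index(env, cells$row, cells$col) %in%
                       cell_index(env, rc$row, rc$col)), , drop = FALSE]
  }
  if (n > nrow(cells))
    stopf("requested %d pseudo-absences but only %d eligible cells", n, nrow(cells))
  set.seed(derive_seed(seed, 66L))
  pick <- cells[sample.int(nrow(cells), n), , drop = FALSE]
  occurrence_set(data.frame(lon = pick$lon, lat = pick$lat,
                            label = "pseudo_absence",
                            row = pick$row, col = pick$col),
                 meta = list(seed = seed, buffer_km = area$buffer_km))
}
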