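#' Project posterior-mean suitability over a domain
#'
#' Evaluates the posterior-mean presence probability on every complete cell
#' of the projection domain (by study design, the largest calibration
#' buffer); cells outside the domain are no-data.
#'
#' @param post A `plateau_posterior`.
#' @param env_norm Normalized [env_stack()] (present-day or future, pushed
#'   through the *same* stored transform).
#' @param domain Logical matrix (e.g. the largest buffer's mask), or `NULL`
#'   for all sea cells.
#' @param thin Draw thinning passed to [posterior_predict()].
#' @return A [suit_map()].
#' @export
project_map <- function(post, env_norm, domain = NULL, thin = 1L) {
  cells <- stack_cells(env_norm, mask = domain, complete_only = TRUE)
  pred <- posterior_predict(post, cells[post$predictors], thin = thin)
  vals <- matrix(NA_real_, length(env_norm$lat), length(env_norm$lon))
  vals[cbind(cells$row, cells$col)] <- pred$mean
  suit_map(vals, env_norm, meta = list(prior_mode = post$prior$mode))
}

#' Binary range map by omission threshold
#'
#' The threshold is the `omission` quantile (default the 10th percentile,
#' linear interpolation) of the suitabilities at the model's own training
#' presences; a cell is suitable (1) iff its suitability is >= the
#' threshold.
#'
#' @param suit A [suit_map()].
#' @param presence_suit Suitability values at the training presences of the
#'   same model replicate.
#' @param omission Omission rate (default 0.10).
#' @return Object of class `binary_map`: list with `cells` (0/1 matrix, `NA`
#'   outside the domain), `threshold`, grid vectors, and provenance.
#' @export
binarize <- function(suit, presence_suit, omission = 0.10) {
  if (!length(presence_suit)) stopf("presence_suit is empty")
  thr <- unname(quantile(presence_suit, omission, type = 7))
  cells <- ifelse(is.na(suit$values), NA_real_, as.numeric(suit$values >= thr))
  structure(list(cells = cells, threshold = thr, omission = omission,
                 lon = suit$lon, lat = suit$lat, meta = suit$meta),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> %d suitable of %d domain cells (threshold %.4f)\n",
              sum(x$cells == 1, na.rm = TRUE), sum(!is.na(x$cells)), x$threshold))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$lon, b$lon)) || !isTRUE(all.equal(a$lat, b$lat)) ||
      !identical(dim(a$cells), dim(b$cells)))
    stopf("binary maps are not on the same grid")
}

#' Jaccard similarity of two binary range maps
#'
#' `|A intersect B| / |A union B|` over suitable cells; two empty maps give
#' 1 (flagged with a warning).
#'
#' @param a,b `binary_map`s on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  check_same_grid(a, b)
  A <- a$cells == 1; B <- b$cells == 1
  A[is.na(A)] <- FALSE; B[is.na(B)] <- FALSE
  uni <- sum(A | B)
  if (uni == 0) {
    warnf("both maps are empty; Jaccard defined as 1")
    return(1)
  }
  sum(A & B) / uni
}

#' Cross-product Jaccard matrix between two sets of binary maps
#'
#' The study design compares 25 replicate predictions per calibration extent,
#' giving a 25 x 25 = 625-entry matrix per extent pair and model type.
#'
#' @param set_a,set_b Lists of `binary_map`s on one grid.
#' @return List with `matrix` (`|set_a| x |set_b|`), `mean` and `se` (SE of
#'   the mean over all entries).
#' @export
pairwise_jaccard <- function(set_a, set_b) {
  if (!length(set_a) || !length(set_b)) stopf("empty map list")
  m <- matrix(NA_real_, length(set_a), length(set_b))
  for (i in seq_along(set_a))
    for (j in seq_along(set_b))
      m[i, j] <- jaccard(set_a[[i]], set_b[[j]])
  list(matrix = m, mean = mean(m), se = stats::sd(m) / sqrt(length(m)))
}

#' Range expansion and contraction between two binary maps
#'
#' Under unlimited dispersal: expansion = newly suitable cells as a
#' percentage of the current range, contraction = lost cells as a percentage
#' of the current range (cell counts, no area weighting unless requested).
#'
#' @param current,future `binary_map`s on the same grid.
#' @param area_weight `"none"` (count cells) or `"cos-lat"` (weight each
#'   cell by the cosine of its latitude, proportional to true cell area on
#'   the equirectangular grid).
#' @return Named vector `c(expansion = %, contraction = %)`.
#' @export
range_change <- function(current, future, area_weight = c("none", "cos-lat")) {
  area_weight <- match.arg(area_weight)
  check_same_grid(current, future)
  A <- current$cells == 1; B <- future$cells == 1
  A[is.na(A)] <- FALSE; B[is.na(B)] <- FALSE
  w <- if (area_weight == "cos-lat")
    matrix(cos(current$lat * pi / 180), nrow(A), ncol(A)) else matrix(1, nrow(A), ncol(A))
  cur <- sum(w[A])
  if (cur == 0) stopf("current range is empty")
  c(expansion = 100 * sum(w[B & !A]) / cur,
    contraction = 100 * sum(w[A & !B]) / cur)
}

#' Southern limit of a binary range map
#'
#' Minimum cell-center latitude among suitable cells.
#'
#' @param map A `binary_map`.
#' @return Latitude in degrees.
#' @export
southern_limit <- function(map) {
  rows <- which(apply(map$cells == 1, 1, any, na.rm = TRUE))
  if (!length(rows)) stopf("binary map has no suitable cells")
  min(map$lat[rows])
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on the paired differences (zero differences dropped,
#' mid-ranks for ties): exact p-value for n <= 25 without ties, normal
#' approximation with continuity correction otherwise — a thin wrapper over
#' [stats::wilcox.test()] returning the V statistic and p-value.
#'
#' @param x,y Paired samples of equal length >= 3.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return Named list with `V`, `p_value`, `n_used` (pairs after dropping
#'   zero differences).
#' @export
paired_wilcoxon <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stopf("x and y must be paired (equal length)")
  if (length(x) < 3) stopf("need >= 3 pairs")
  d <- x - y
  if (all(d == 0)) stopf("all paired differences are zero")
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                     alternative = alternative,
                                     correct = TRUE))
  list(V = unname(wt$statistic), p_value = wt$p.value, n_used = sum(d != 0))
}

#' Write / read a binary map as an ESRI ASCII grid
#'
#' The threshold and provenance go to a JSON sidecar.
#' @param map A `binary_map`.
#' @param prefix Path prefix.
#' @return `read_binary_map` returns a `binary_map`.
#' @export
write_binary_map <- function(map, prefix) {
  env_like <- list(lon = map$lon, lat = map$lat)
  write_ascii_grid(map$cells, env_like, paste0(prefix, ".asc"))
  jsonlite::write_json(list(threshold = map$threshold, omission = map$omission,
                            meta = map$meta),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_binary_map
#' @export
read_binary_map <- function(prefix) {
  g <- read_ascii_grid(paste0(prefix, ".asc"))
  sc <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(cells = g$values, threshold = sc$threshold,
                 omission = sc$omission, lon = g$lon, lat = g$lat,
                 meta = as.list(sc$meta)),
            class = "binary_map")
}
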