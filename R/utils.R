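#' @useDynLib plateauSDM, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm runif rnorm rbinom quantile median cor var
#'   complete.cases lm plogis qlogis setNames wilcox.test
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of radius 6371 km, the convention
#' used throughout the package (thinning, buffers, distance-to-shore).
#'
#' @param p1,p2 Two-column matrices (or length-2 vectors) of lon/lat in
#'   decimal degrees. Rows are recycled as in [geosphere::distHaversine()].
#' @return Numeric vector of distances in km.
#' @export
gc_dist_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371) # r in km -> result in km
}

# Full pairwise distance matrix (km) for a lon/lat matrix.
gc_dist_matrix_km <- function(pts) {
  geosphere::distm(pts, fun = function(a, b) geosphere::distHaversine(a, b, r = 6371))
}

# Cross distances (km): rows of a x rows of b.
gc_cross_dist_km <- function(a, b) {
  geosphere::distm(a, b, fun = function(p, q) geosphere::distHaversine(p, q, r = 6371))
}

# Gaussian-kernel smoothing of a matrix by separable 1-D convolution with
# edge renormalization (kernel mass outside the grid is dropped, weights
# rescaled so a constant field stays constant).
smooth_matrix <- function(m, kernel_sd) {
  if (kernel_sd <= 0) return(m)
  half <- max(1L, ceiling(3 * kernel_sd))
  k <- dnorm(seq(-half, half), sd = kernel_sd)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      w <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(v[lo:hi] * w) / sum(w)
    }
    out
  }
  out <- apply(m, 2L, conv1)
  if (!is.matrix(out)) out <- matrix(out, nrow(m), ncol(m))
  out <- t(apply(out, 1L, conv1))
  if (!identical(dim(out), dim(m))) out <- matrix(out, nrow(m), ncol(m))
  out
}

# Smoothed standard-normal random field on an n_rows x n_cols grid,
# rescaled back to unit marginal variance (smoothing shrinks the variance).
random_field <- function(n_rows, n_cols, kernel_sd = 3) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- smooth_matrix(z, kernel_sd)
  s <- stats::sd(f)
  if (s > 0) f <- f / s
  f
}

# Rescale a field to the range [lo, hi].
rescale_range <- function(m, lo, hi) {
  r <- range(m, na.rm = TRUE)
  if (diff(r) == 0) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - r[1]) / diff(r) * (hi - lo)
}

# Deterministic seed mixing for derived random streams; keeps results
# in [1, 2^31 - 2] so they are valid R integer seeds.
derive_seed <- function(master, ...) {
  idx <- c(...)
  x <- as.double(master %% 2147483647)
  for (i in idx) {
    x <- (x * 48271 + as.double(i) * 2246822519 + 1013904223) %% 2147483647
  }
  as.integer(max(1, x))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
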