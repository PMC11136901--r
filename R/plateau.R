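#' Plateau (trapezoidal envelope) model parameters
#'
#' The per-predictor response is a trapezoid on the logit scale: zero penalty
#' on the plateau `[c1, c2]` and linear descents with slopes `b1` (below
#' `c1`) and `b2` (above `c2`), all in normalized predictor units. A single
#' global intercept `beta0` is the apex of the linear predictor: the model is
#' `p = plogis(beta0 + sum_j f_j(x_j))`, so the response attains its maximum
#' `plogis(beta0)` exactly when every predictor sits on its plateau.
#'
#' @param intercept Apex of the linear predictor (logit units).
#' @param params data.frame with columns `predictor`, `c1`, `c2`, `b1`, `b2`
#'   (one row per modelled predictor); requires `c1 <= c2` and slopes >= 0.
#' @return Object of class `plateau_params`.
#' @export
plateau_params <- function(intercept, params) {
  stopifnot(all(c("predictor", "c1", "c2", "b1", "b2") %in% names(params)))
  if (any(params$c1 > params$c2)) stopf("c1 must be <= c2 for every predictor")
  if (any(params$b1 < 0 | params$b2 < 0)) stopf("slopes must be >= 0")
  structure(list(intercept = intercept,
                 params = as.data.frame(params, stringsAsFactors = FALSE)),
            class = "plateau_params")
}

as_plateau_params <- function(x) {
  if (inherits(x, "plateau_params")) return(x)
  stopf("expected a plateau_params object")
}

#' @export
print.plateau_params <- function(x, ...) {
  cat(sprintf("<plateau_params> intercept (apex) = %.3f\n", x$intercept))
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' Trapezoidal penalty of a single predictor
#'
#' `f(x) = -b1 * max(0, c1 - x) - b2 * max(0, x - c2)`: zero on the plateau
#' `[c1, c2]`, piecewise-linear and continuous, always <= 0 (logit units).
#'
#' @param x Normalized predictor values (may lie outside `[0, 1]`, e.g.
#'   future climate layers).
#' @param c1,c2 Plateau edges (`c1 <= c2`).
#' @param b1,b2 Descent slopes (>= 0).
#' @return Penalty values, same length as `x`.
#' @export
plateau_response <- function(x, c1, c2, b1, b2) {
  if (any(c1 > c2)) stopf("c1 must be <= c2")
  if (any(b1 < 0 | b2 < 0)) stopf("slopes must be >= 0")
  -b1 * pmax(0, c1 - x) - b2 * pmax(0, x - c2)
}

#' Presence probability of the plateau model
#'
#' @param X data.frame or matrix of normalized predictor values with columns
#'   named as in `params$params$predictor` (extra columns ignored).
#' @param params A [plateau_params()].
#' @return Vector of probabilities in (0, 1), one per row of `X`.
#' @export
presence_probability <- function(X, params) {
  params <- as_plateau_params(params)
  pp <- params$params
  missing <- setdiff(pp$predictor, colnames(X))
  if (length(missing))
    stopf("missing predictor(s): %s", paste(missing, collapse = ", "))
  X <- as.matrix(as.data.frame(X)[pp$predictor])
  eta <- rep(params$intercept, nrow(X))
  for (j in seq_len(nrow(pp)))
    eta <- eta + plateau_response(X[, j], pp$c1[j], pp$c2[j], pp$b1[j], pp$b2[j])
  plogis(eta)
}

#' Bernoulli log-likelihood of labelled cells
#'
#' `sum(log p)` over presences plus `sum(log(1 - p))` over pseudo-absences,
#' with probabilities clamped to `[1e-12, 1 - 1e-12]` so the result stays
#' finite under extreme parameter draws.
#'
#' @param X Normalized predictor values (see [presence_probability()]).
#' @param y 0/1 labels (1 = presence), one per row of `X`.
#' @param params A [plateau_params()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(X, y, params) {
  if (!length(y)) stopf("no data")
  p <- presence_probability(X, params)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(ifelse(y == 1, log(p), log1p(-p)))
}

#' Simulate labelled data from a known plateau response
#'
#' Draws predictor vectors uniformly on the normalized cube and labels each
#' point by a Bernoulli draw with the teacher's presence probability — the
#' model's own data-generating process, used for parameter-recovery
#' experiments.
#'
#' @param truth A [plateau_params()].
#' @param n Number of points.
#' @param seed Integer seed.
#' @param x_range Range the predictors are drawn from (normalized units).
#' @return List with `X` (data.frame) and `y` (0/1 vector).
#' @export
simulate_labelled <- function(truth, n, seed = 1L, x_range = c(0, 1)) {
  truth <- as_plateau_params(truth)
  preds <- truth$params$predictor
  set.seed(derive_seed(seed, 77L))
  X <- as.data.frame(matrix(runif(n * length(preds), x_range[1], x_range[2]),
                            n, length(preds)))
  names(X) <- preds
  p <- presence_probability(X, truth)
  list(X = X, y = rbinom(n, 1, p))
}
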