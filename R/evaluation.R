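#' Spatial block fold assignment
#'
#' Splits the bounding box of the records into an `n_rows x n_cols` grid of
#' equal lat/lon blocks and randomly allocates the non-empty blocks to `k`
#' folds, greedily balancing per-fold presence counts (each fold's count
#' deviates from the balanced share by at most one block's worth). Records
#' in the same block always share a fold.
#'
#' @param points data.frame with `lon`, `lat` and optionally `label`
#'   (presences drive the balancing; all records are assigned).
#' @param n_rows,n_cols Block grid (default 10 x 10).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param max_retry Reshuffles allowed before giving up when a fold ends up
#'   without presences.
#' @return Object of class `fold_assignment`: integer fold id per record,
#'   with the block grid spec as attributes.
#' @export
spatial_block_folds <- function(points, n_rows = 10, n_cols = 10, k = 5,
                                seed = 1L, max_retry = 20L) {
  if (nrow(points) < k) stopf("fewer records than folds")
  rx <- range(points$lon); ry <- range(points$lat)
  if (diff(rx) == 0 || diff(ry) == 0) stopf("records span a degenerate bounding box")
  bx <- pmin(1L + findInterval(points$lon, seq(rx[1], rx[2], length.out = n_cols + 1),
                               rightmost.closed = TRUE, all.inside = TRUE) - 1L, n_cols)
  by <- pmin(1L + findInterval(points$lat, seq(ry[1], ry[2], length.out = n_rows + 1),
                               rightmost.closed = TRUE, all.inside = TRUE) - 1L, n_rows)
  block <- (by - 1L) * n_cols + bx
  is_pres <- if ("label" %in% names(points)) points$label == "presence"
             else rep(TRUE, nrow(points))
  blocks <- sort(unique(block))
  if (length(blocks) < k) stopf("only %d non-empty blocks for %d folds",
                                length(blocks), k)
  npres <- vapply(blocks, function(b) sum(is_pres & block == b), numeric(1))
  set.seed(derive_seed(seed, 99L))
  for (try in seq_len(max_retry)) {
    ord <- order(-npres + runif(length(blocks)) * 0.5) # shuffle ties, big first
    fold_of_block <- integer(length(blocks))
    load <- numeric(k)
    for (b in ord) {
      f <- which.min(load + runif(k) * 1e-9)
      fold_of_block[b] <- f
      load[f] <- load[f] + npres[b]
    }
    fold <- fold_of_block[match(block, blocks)]
    if (all(vapply(seq_len(k), function(f) sum(is_pres & fold == f), numeric(1)) > 0))
      return(structure(fold, class = "fold_assignment", k = k,
                       n_rows = n_rows, n_cols = n_cols, block = block))
  }
  stopf("could not allocate blocks so that every fold holds a presence")
}

#' Continuous Boyce index
#'
#' Predicted-to-expected ratio curve: `res` windows of width
#' `window_frac x range(bg_suit)` centered at evenly spaced points spanning
#' the background suitability range; in each window `P` is the share of
#' presence suitabilities and `E` the share of background suitabilities;
#' windows with `E = 0` are dropped and the index is the Spearman rank
#' correlation between `P/E` and the window center, in `[-1, 1]`.
#'
#' @param pres_suit Suitability at presence records.
#' @param bg_suit Suitability over the background (all calibration-area
#'   cells).
#' @param window_frac Window width as a fraction of the background range.
#' @param res Number of window centers.
#' @return Scalar Boyce index.
#' @export
boyce_index <- function(pres_suit, bg_suit, window_frac = 0.1, res = 100) {
  if (!length(pres_suit) || !length(bg_suit)) stopf("empty input")
  r <- range(bg_suit)
  width <- window_frac * diff(r)
  centers <- seq(r[1], r[2], length.out = res)
  pe <- vapply(centers, function(ct) {
    lo <- ct - width / 2; hi <- ct + width / 2
    E <- mean(bg_suit >= lo & bg_suit <= hi)
    if (E == 0) return(NA_real_)
    mean(pres_suit >= lo & pres_suit <= hi) / E
  }, numeric(1))
  keep <- !is.na(pe)
  if (sum(keep) < 3) stopf("Boyce index undefined: fewer than 3 usable windows")
  cor(pe[keep], centers[keep], method = "spearman")
}

#' Spatial block cross-validation of a plateau model
#'
#' For each fold: fit on the records of the other folds and score the
#' withheld presences with the Boyce index against the calibration-area
#' background suitability.
#'
#' @param data An [occurrence_set()] with both labels (grid-linked).
#' @param env_norm Normalized [env_stack()].
#' @param area [calib_area()] supplying the Boyce background cells.
#' @param prior `prior_spec` for the refits.
#' @param cfg [mcmc_config()]; per-fold seeds are derived from `cfg$seed`.
#' @param folds A `fold_assignment` for the rows of `data`.
#' @return Numeric vector of per-fold Boyce values (length `k`).
#' @export
cross_validate <- function(data, env_norm, area, prior, cfg, folds) {
  k <- attr(folds, "k")
  if (k < 2) stopf("need k >= 2 folds")
  bg <- stack_cells(env_norm, mask = area$mask, complete_only = TRUE)
  vapply(seq_len(k), function(f) {
    train <- data[folds != f, , drop = FALSE]
    test_pres <- presences(data[folds == f, , drop = FALSE])
    if (length(unique(train$label)) < 2)
      stopf("fold %d leaves a training split without both labels", f)
    mf <- model_frame(train, env_norm, prior$predictors)
    fit <- fit_mcmc(mf, prior, mcmc_config(
      n_chains = cfg$n_chains, n_iter = cfg$n_iter, n_warmup = cfg$n_warmup,
      seed = derive_seed(cfg$seed, 17L, f), adapt_batch = cfg$adapt_batch,
      target_accept = cfg$target_accept, init_jitter = cfg$init_jitter))
    pres_mf <- model_frame(test_pres, env_norm, prior$predictors)
    pres_suit <- posterior_predict(fit, pres_mf$X)$mean
    bg_suit <- posterior_predict(fit, bg[prior$predictors])$mean
    boyce_index(pres_suit, bg_suit)
  }, numeric(1))
}

#' Permutation variable importance
#'
#' For each predictor: permute its column, recompute the posterior-mean
#' predictions and report `1 - cor(intact, permuted)` (Pearson), averaged
#' over `n_perm` permutations and clipped to `[0, 1]`. Constant predictions
#' give importance 0 with a warning.
#'
#' @param post A `plateau_posterior`.
#' @param X Normalized predictor data (training or background cells).
#' @param n_perm Number of permutations (default 5).
#' @param seed Integer seed.
#' @param thin Draw thinning passed to [posterior_predict()].
#' @return Named numeric vector of importances in `[0, 1]`.
#' @export
permutation_importance <- function(post, X, n_perm = 5, seed = 1L, thin = 1L) {
  X <- as.data.frame(X)[post$predictors]
  base <- posterior_predict(post, X, thin = thin)$mean
  if (stats::sd(base) == 0) {
    warnf("constant predictions; importances undefined, reported as 0")
    return(setNames(rep(0, length(post$predictors)), post$predictors))
  }
  set.seed(derive_seed(seed, 23L))
  imp <- vapply(post$predictors, function(nm) {
    drops <- vapply(seq_len(n_perm), function(i) {
      Xp <- X
      Xp[[nm]] <- sample(Xp[[nm]])
      perm <- posterior_predict(post, Xp, thin = thin)$mean
      if (stats::sd(perm) == 0) return(1)
      1 - cor(base, perm)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  pmin(pmax(imp, 0), 1)
}

#' Marginal response curve of one predictor
#'
#' Varies the predictor over the observed range extended to include its hard
#' limit (when a transform + limit value are supplied), holding all other
#' predictors at their median over the reference cells, and evaluates the
#' posterior-mean probability with a central 95% band.
#'
#' @param post A `plateau_posterior`.
#' @param predictor Predictor name.
#' @param ref_cells Normalized reference cells (e.g. the calibration-area
#'   cells) supplying medians and the observed range.
#' @param n_grid Number of grid points (default 100).
#' @param extend_to Optional normalized value the grid must reach (e.g. the
#'   normalized hard limit).
#' @param transform Optional `norm_transform` to also report physical units.
#' @return data.frame with `value` (normalized), optional `physical`, `mean`,
#'   `lower`, `upper`.
#' @export
response_curve <- function(post, predictor, ref_cells, n_grid = 100,
                           extend_to = NULL, transform = NULL) {
  if (!predictor %in% post$predictors) stopf("unknown predictor '%s'", predictor)
  ref_cells <- as.data.frame(ref_cells)[post$predictors]
  lo <- min(ref_cells[[predictor]]); hi <- max(ref_cells[[predictor]])
  if (!is.null(extend_to)) { lo <- min(lo, extend_to); hi <- max(hi, extend_to) }
  grid <- seq(lo, hi, length.out = n_grid)
  X <- as.data.frame(lapply(ref_cells, median))[rep(1, n_grid), , drop = FALSE]
  X[[predictor]] <- grid
  pred <- posterior_predict(post, X)
  out <- data.frame(value = grid, mean = pred$mean, lower = pred$lower,
                    upper = pred$upper)
  if (!is.null(transform))
    out$physical <- normalize_values(grid, transform, predictor, invert = TRUE)
  out
}
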