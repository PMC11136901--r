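#' MCMC configuration
#'
#' Defaults follow the study design: two parallel chains started from the
#' same initial values, 5000 iterations each of which the first 4000 are
#' warm-up, leaving 1000 retained draws per chain.
#'
#' @param n_chains Number of chains (>= 2).
#' @param n_iter Iterations per chain.
#' @param n_warmup Warm-up (burn-in) iterations, `< n_iter`; step sizes adapt
#'   only during warm-up.
#' @param seed Integer seed; fits are bitwise reproducible from it.
#' @param adapt_batch Adaptation batch length (iterations).
#' @param target_accept Target acceptance rate of the component-wise
#'   random-walk proposals.
#' @param init_jitter SD of optional N(0, sd) jitter added to the shared
#'   initial values per chain; 0 (the default) reproduces the
#'   same-initial-values convention.
#' @param link Link function; only `"logit"` is implemented.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_iter = 5000, n_warmup = 4000,
                        seed = 1L, adapt_batch = 50, target_accept = 0.44,
                        init_jitter = 0, link = "logit") {
  if (n_chains < 2) stopf("n_chains must be >= 2")
  if (n_warmup >= n_iter) stopf("n_warmup (%d) must be < n_iter (%d)",
                                n_warmup, n_iter)
  link <- match.arg(link, "logit")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup), seed = as.integer(seed),
                 adapt_batch = as.integer(adapt_batch),
                 target_accept = target_accept, init_jitter = init_jitter,
                 link = link),
            class = "mcmc_config")
}

# slot bookkeeping ----------------------------------------------------------

slot_names <- function(predictors)
  c(as.vector(t(outer(predictors, c("c1", "c2", "b1", "b2"), paste, sep = "."))),
    "intercept")

# encode the prior table into flat arrays for the C++ sampler
encode_prior <- function(prior) {
  tab <- prior$table
  S <- nrow(tab)
  kind <- integer(S); theta_idx <- integer(S)
  fixed_val <- numeric(S); limit_x <- numeric(S)
  for (r in seq_len(S)) {
    kind[r] <- switch(tab$role[r], free = 0L, fixed = 1L, linked = 2L)
    theta_idx[r] <- if (tab$role[r] == "free") tab$theta_idx[r] - 1L else -1L
    fixed_val[r] <- if (tab$role[r] == "fixed") tab$value[r] else 0
    limit_x[r] <- if (tab$role[r] == "linked") tab$limit_x[r] else 0
  }
  free <- tab[tab$role == "free", ]
  ptype <- match(free$dist, c("unif", "halfnorm", "norm")) - 1L
  list(kind = kind, theta_idx = theta_idx, fixed_val = fixed_val,
       limit_x = limit_x, ptype = ptype,
       p1 = ifelse(is.na(free$p1), 0, free$p1),
       p2 = ifelse(is.na(free$p2), 1, free$p2),
       lower = free$lower, upper = free$upper,
       free_names = paste(ifelse(is.na(free$predictor), "", free$predictor),
                          free$param, sep = ".") |> sub("^\\.", "", x = _))
}

# assemble free-parameter draws into the full slot matrix
assemble_draws <- function(theta, prior) {
  tab <- prior$table
  S <- nrow(tab)
  out <- matrix(NA_real_, nrow(theta), S,
                dimnames = list(NULL, slot_names(prior$predictors)))
  beta_idx <- which(tab$param == "intercept")
  for (r in seq_len(S)) {
    out[, r] <- switch(tab$role[r],
      free = theta[, tab$theta_idx[r]],
      fixed = tab$value[r],
      linked = NA_real_)
  }
  beta0 <- out[, beta_idx]
  for (r in which(tab$role == "linked")) {
    edge_param <- if (tab$param[r] == "b2") "c2" else "c1"
    ei <- which(tab$predictor == tab$predictor[r] & tab$param == edge_param)
    gap <- if (tab$param[r] == "b2") tab$limit_x[r] - out[, ei]
           else out[, ei] - tab$limit_x[r]
    out[, r] <- (beta0 - prior$L) / gap
  }
  out
}

# build (X, y) from presence/pseudo-absence records + normalized stack
#' Assemble a labelled model frame from occurrences and a normalized stack
#'
#' Looks up the normalized predictor values at each record's grid cell and
#' returns the design matrix and 0/1 labels used by [fit_mcmc()].
#'
#' @param occ An [occurrence_set()] containing both labels (e.g. presences
#'   plus pseudo-absences, rbind-ed).
#' @param env_norm Normalized [env_stack()] (the `$env` of
#'   [normalize_predictors()]).
#' @param predictors Predictors to include; default all layers.
#' @return List with `X` (data.frame) and `y` (0/1).
#' @export
model_frame <- function(occ, env_norm, predictors = names(env_norm$layers)) {
  rc <- if (all(c("row", "col") %in% names(occ))) occ[c("row", "col")]
        else snap_to_grid(env_norm, occ$lon, occ$lat)
  X <- as.data.frame(lapply(setNames(predictors, predictors), function(nm)
    env_norm$layers[[nm]][cbind(rc$row, rc$col)]))
  keep <- complete.cases(X)
  list(X = X[keep, , drop = FALSE],
       y = as.integer(occ$label == "presence")[keep])
}

#' Fit the Bayesian plateau model by MCMC
#'
#' Samples the posterior of the plateau parameters under the given prior
#' specification using an adaptive component-wise random-walk Metropolis
#' sampler (step sizes tuned toward a 0.44 acceptance rate during warm-up,
#' then frozen). Deterministically linked slopes are recomputed inside every
#' likelihood evaluation, so all retained draws satisfy the plateau
#' constraints exactly.
#'
#' @param data List with `X` (normalized predictor data.frame/matrix, columns
#'   named as `prior$predictors`) and `y` (0/1 labels); both labels must be
#'   present.
#' @param prior A `prior_spec` from [build_prior()].
#' @param cfg An [mcmc_config()].
#' @return Object of class `plateau_posterior`: per-chain matrices of
#'   assembled parameter draws (`n_iter - n_warmup` rows each), acceptance
#'   rates, the prior and config, and convergence diagnostics.
#' @export
fit_mcmc <- function(data, prior, cfg = mcmc_config()) {
  X <- as.matrix(as.data.frame(data$X)[prior$predictors])
  y <- as.integer(data$y)
  if (length(unique(y)) < 2) stopf("data must contain both labels")
  enc <- encode_prior(prior)
  init <- prior_inits(prior)
  set.seed(cfg$seed)
  res <- plateau_mcmc_cpp(X, y, enc$kind, enc$theta_idx, enc$fixed_val,
                          enc$limit_x, enc$ptype, enc$p1, enc$p2, enc$lower,
                          enc$upper, init, prior$L, cfg$n_chains, cfg$n_iter,
                          cfg$n_warmup, cfg$adapt_batch, cfg$target_accept,
                          cfg$init_jitter)
  chains <- lapply(res$chains, function(th) {
    colnames(th) <- enc$free_names
    assemble_draws(th, prior)
  })
  post <- structure(list(chains = chains, free_names = enc$free_names,
                         prior = prior, config = cfg,
                         accept_rate = res$accept_rate,
                         predictors = prior$predictors),
                    class = "plateau_posterior")
  post$diagnostics <- convergence_diagnostics(post, warn = FALSE)
  post
}

#' @export
print.plateau_posterior <- function(x, ...) {
  cat(sprintf("<plateau_posterior> %d chains x %d retained draws, %d predictors (%s priors)\n",
              length(x$chains), nrow(x$chains[[1]]), length(x$predictors),
              x$prior$mode))
  if (!is.null(x$diagnostics))
    cat(sprintf("  max split R-hat = %.3f, min ESS = %.0f\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

# all retained draws, chains stacked
posterior_draws <- function(post) do.call(rbind, post$chains)

# one assembled draw (slot-ordered vector) -> plateau_params
assemble_to_params <- function(row, predictors) {
  m <- matrix(row[seq_len(4 * length(predictors))], ncol = 4, byrow = TRUE)
  plateau_params(unname(row[4 * length(predictors) + 1]),
                 data.frame(predictor = predictors, c1 = m[, 1], c2 = m[, 2],
                            b1 = m[, 3], b2 = m[, 4]))
}

#' Posterior summaries of the plateau parameters
#'
#' @param object A `plateau_posterior`.
#' @param prob Central credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return data.frame with posterior mean, median and interval bounds per
#'   parameter (assembled slots, including fixed and linked ones).
#' @export
summary.plateau_posterior <- function(object, prob = 0.95, ...) {
  d <- posterior_draws(object)
  a <- (1 - prob) / 2
  data.frame(parameter = colnames(d), mean = colMeans(d),
             median = apply(d, 2, median),
             lower = apply(d, 2, quantile, a),
             upper = apply(d, 2, quantile, 1 - a), row.names = NULL)
}

#' Posterior predictive presence probability
#'
#' Averages the plateau presence probability over the retained draws and
#' returns central 95% intervals from the draw quantiles.
#'
#' @param post A `plateau_posterior`.
#' @param X Normalized predictor values (data.frame/matrix with the model's
#'   predictor columns), e.g. from [stack_cells()] on a normalized stack.
#' @param thin Keep every `thin`-th draw (1 = all).
#' @return data.frame with `mean`, `lower`, `upper` per row of `X`.
#' @export
posterior_predict <- function(post, X, thin = 1L) {
  Xm <- as.matrix(as.data.frame(X)[post$predictors])
  d <- posterior_draws(post)
  if (thin > 1L) d <- d[seq(1L, nrow(d), by = thin), , drop = FALSE]
  P <- plateau_predict_cpp(d, Xm)
  data.frame(mean = colMeans(P),
             lower = apply(P, 2, quantile, 0.025),
             upper = apply(P, 2, quantile, 0.975))
}

# convergence ---------------------------------------------------------------

split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(v) {
    n <- floor(length(v) / 2)
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via the initial-positive-sequence estimator on the
# chain-averaged autocorrelations
ess_basic <- function(chain_list) {
  m <- length(chain_list); n <- length(chain_list[[1]])
  W <- mean(vapply(chain_list, var, numeric(1)))
  B <- n * var(vapply(chain_list, mean, numeric(1)))
  varplus <- (n - 1) / n * W + (if (m > 1) B / n else 0)
  if (varplus == 0) return(NA_real_)
  lag_max <- min(n - 2L, 200L)
  acov <- sapply(chain_list, function(v)
    stats::acf(v, lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)[-1]) / varplus
  # sum consecutive pairs while positive
  s <- 0; t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  min(m * n / (1 + 2 * s), m * n)
}

#' Convergence diagnostics for a plateau posterior
#'
#' Split R-hat and effective sample size per free parameter; warns (does not
#' fail) when any R-hat exceeds 1.1.
#'
#' @param post A `plateau_posterior` with >= 2 chains.
#' @param warn Emit the R-hat warning (default `TRUE`).
#' @return data.frame with `parameter`, `rhat`, `ess`.
#' @export
convergence_diagnostics <- function(post, warn = TRUE) {
  if (length(post$chains) < 2) stopf("need >= 2 chains for diagnostics")
  nms <- post$free_names
  out <- data.frame(parameter = nms, rhat = NA_real_, ess = NA_real_)
  for (i in seq_along(nms)) {
    vals <- lapply(post$chains, function(ch) ch[, match_free_col(post, nms[i])])
    out$rhat[i] <- split_rhat(vals)
    out$ess[i] <- ess_basic(vals)
  }
  if (warn && any(out$rhat > 1.1, na.rm = TRUE))
    warnf("split R-hat > 1.1 for: %s",
          paste(out$parameter[which(out$rhat > 1.1)], collapse = ", "))
  out
}

# free names are "<predictor>.<param>" or "intercept"; these match the
# assembled slot columns directly
match_free_col <- function(post, nm) {
  match(nm, colnames(post$chains[[1]]))
}

#' Save / load a posterior as CSV + JSON sidecar
#'
#' One row per retained draw (a `chain` column separates chains) and a JSON
#' sidecar with the sampler config, prior mode and diagnostics.
#'
#' @param post A `plateau_posterior`.
#' @param prefix Path prefix (`<prefix>.csv`, `<prefix>.json`).
#' @return The CSV path, invisibly.
#' @export
write_posterior <- function(post, prefix) {
  d <- do.call(rbind, lapply(seq_along(post$chains), function(i)
    cbind(chain = i, as.data.frame(post$chains[[i]]))))
  write.csv(d, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(post$config), prior_mode = post$prior$mode,
         predictors = post$predictors,
         diagnostics = post$diagnostics),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".csv"))
}
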