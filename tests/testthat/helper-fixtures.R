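# shared fixtures, memoized so expensive objects are built once per run
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small synthetic landscape with ground truth on the global sea-cell scale
tiny_landscape <- function() memo("tiny", {
  cfg <- landscape_config(n_rows = 30, n_cols = 40, seed = 42)
  env <- simulate_landscape(cfg)
  transform <- plateauSDM:::global_transform(env)
  truth <- default_true_response(transform)
  suit <- true_suitability(env, truth, transform)
  list(cfg = cfg, env = env, transform = transform, truth = truth, suit = suit)
})

# an all-sea stack (one land cell so the mask is non-degenerate) with given
# layer matrices, on a 1-degree grid
flat_env <- function(layers, n_rows = 15, n_cols = 20) {
  sea <- matrix(TRUE, n_rows, n_cols)
  sea[1, 1] <- FALSE
  env_stack(lon = seq(100.5, by = 1, length.out = n_cols),
            lat = seq(20.5, by = 1, length.out = n_rows),
            sea = sea, layers = layers)
}

# three-predictor teacher with signal everywhere; edges well inside (0, 1)
recovery_truth <- function() plateau_params(2, data.frame(
  predictor = c("temp_mean", "depth", "salinity"),
  c1 = c(0.35, 0.25, 0.40), c2 = c(0.65, 0.55, 0.70),
  b1 = c(12, 20, 8), b2 = c(25, 15, 10)))

# a quick fit on tabular data simulated from recovery_truth()
small_tabular_fit <- function() memo("small_fit", {
  truth <- recovery_truth()
  d <- simulate_labelled(truth, 400, seed = 9)
  prior <- build_prior("naive", truth$params$predictor)
  fit <- fit_mcmc(d, prior, mcmc_config(n_iter = 1200, n_warmup = 900, seed = 4))
  list(truth = truth, data = d, prior = prior, fit = fit)
})

# prepared landscape data: presences, buffers, normalized stack, model frame
prepared_landscape <- function() memo("prep", {
  L <- tiny_landscape()
  occ <- sample_occurrences(L$suit, 70, seed = 3)
  occ <- clean_records(occ, L$env)
  occ <- thin_records(occ, 20, seed = 2)
  a_small <- buffer_area(occ, 1000, L$env)
  a_big <- buffer_area(occ, 2000, L$env)
  norm <- normalize_predictors(L$env, a_big)
  pa <- draw_pseudo_absences(a_big, L$env, occ, seed = 5)
  all_occ <- occurrence_set(rbind(occ[c("lon", "lat", "label", "row", "col")],
                                  pa[c("lon", "lat", "label", "row", "col")]))
  c(L, list(occ = occ, a_small = a_small, a_big = a_big,
            env_norm = norm$env, transform_area = norm$transform,
            pa = pa, all_occ = all_occ,
            mf = model_frame(all_occ, norm$env)))
})

# a reduced-MCMC landscape fit per prior mode
landscape_fit <- function(mode) memo(paste0("lfit_", mode), {
  P <- prepared_landscape()
  prior <- build_prior(mode, names(P$env$layers),
                       transform = P$transform_area)
  fit_mcmc(P$mf, prior, mcmc_config(n_iter = 1200, n_warmup = 900, seed = 21))
})

# fabricate a posterior object from raw per-chain draw matrices (assembled
# slot layout) for diagnostics / prediction unit tests
fake_posterior <- function(chains, predictors, free_names = colnames(chains[[1]]),
                           prior = NULL) {
  structure(list(chains = chains, free_names = free_names,
                 predictors = predictors, prior = prior,
                 config = NULL, diagnostics = NULL),
            class = "plateau_posterior")
}
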