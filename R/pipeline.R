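#' Default physiologically grounded ground truth
#'
#' The synthetic "teacher" response used by the experiment pipeline: the
#' temperature plateau sits on the normalized image of the 15-18 degC
#' optimum with its descending slope reaching the absence floor at 26 degC;
#' the depth plateau is the 0-40 m optimum with the slope reaching the floor
#' at 200 m; temperature range, salinity, current velocity and distance to
#' shore carry no signal (zero slopes), mirroring a species limited by
#' temperature and depth only.
#'
#' @param transform `norm_transform` mapping physical units onto the
#'   normalized scale of the landscape at hand.
#' @param intercept Apex of the linear predictor (default 2.5, a maximal
#'   suitability of ~0.92).
#' @param floor Absence floor at the hard limits (default 0.01).
#' @param b1_temp Ascending temperature slope (logit units per normalized
#'   unit).
#' @return A [plateau_params()] covering the six landscape predictors.
#' @export
default_true_response <- function(transform, intercept = 2.5, floor = 0.01,
                                  b1_temp = 8) {
  L <- qlogis(floor)
  nv <- function(v, nm) normalize_values(v, transform, nm)
  t1 <- nv(15, "temp_mean"); t2 <- nv(18, "temp_mean"); t26 <- nv(26, "temp_mean")
  d1 <- nv(0, "depth"); d2 <- nv(40, "depth"); d200 <- nv(200, "depth")
  plateau_params(intercept, data.frame(
    predictor = c("depth", "dist_shore", "temp_mean", "temp_range",
                  "salinity", "current"),
    c1 = c(d1, 0, t1, 0.2, 0.3, 0.3),
    c2 = c(d2, 1, t2, 0.8, 0.7, 0.7),
    b1 = c(0, 0, b1_temp, 0, 0, 0),
    b2 = c((intercept - L) / (d200 - d2), 0, (intercept - L) / (t26 - t2),
           0, 0, 0)))
}

# normalize a stack through a stored transform (no clipping)
normalize_stack <- function(env, transform) {
  out <- env
  for (nm in names(env$layers)) {
    i <- match(nm, transform$layer)
    if (is.na(i)) stopf("transform does not cover layer '%s'", nm)
    out$layers[[nm]] <- (env$layers[[nm]] - transform$offset[i]) / transform$scale[i]
  }
  out$meta$normalized <- TRUE
  out
}

#' Experiment run configuration
#'
#' Assembles and validates the configuration of the full comparison
#' experiment. Defaults reproduce the study design: three calibration
#' buffers (1000/1500/2000 km), 25 pseudo-absence replicates per buffer and
#' model type, 20-km thinning, 10% omission threshold, VIF threshold 10,
#' and the default MCMC schedule (2 chains, 5000 iterations, 4000 warm-up).
#'
#' @param landscape Named list of [landscape_config()] overrides.
#' @param buffers_km Strictly increasing buffer radii (km).
#' @param replicates Pseudo-absence replicates per buffer and type (>= 1).
#' @param model_types Subset of `c("naive", "informed")`.
#' @param mcmc Named list of [mcmc_config()] overrides.
#' @param constraints List of [physio_constraint()]; default the shipped
#'   sea-cucumber analogue.
#' @param n_presences Presences sampled from the true response.
#' @param bias_strength Sampling-bias exponent (0 = unbiased).
#' @param truncation_temp Optional degC cutoff: presences are only sampled
#'   from cells with `temp_mean` at or below it (warm-truncated survey).
#' @param thin_km,omission,vif_threshold Preparation thresholds.
#' @param future Named list: `delta_temp`, `delta_range`, `warming_sd`.
#' @param evaluate `"none"` or `"first"` (block-CV Boyce for replicate 1 of
#'   every buffer x type).
#' @param seed Master seed; all stage seeds derive from it.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(landscape = list(), buffers_km = c(1000, 1500, 2000),
                       replicates = 25, model_types = c("naive", "informed"),
                       mcmc = list(), constraints = default_constraints(),
                       n_presences = 150, bias_strength = 0,
                       truncation_temp = NULL, thin_km = 20, omission = 0.10,
                       vif_threshold = 10,
                       future = list(delta_temp = 2, delta_range = 0,
                                     warming_sd = 0.3),
                       evaluate = "none", seed = 1L) {
  cfg <- structure(list(landscape = landscape, buffers_km = buffers_km,
                        replicates = as.integer(replicates),
                        model_types = model_types, mcmc = mcmc,
                        constraints = constraints,
                        n_presences = as.integer(n_presences),
                        bias_strength = bias_strength,
                        truncation_temp = truncation_temp,
                        thin_km = thin_km, omission = omission,
                        vif_threshold = vif_threshold, future = future,
                        evaluate = evaluate, seed = as.integer(seed)),
                   class = "run_config")
  validate_config(cfg)
}

#' Load an experiment configuration from YAML
#'
#' Missing keys take the study defaults; an empty file yields the full
#' default configuration. All violations are reported at once.
#'
#' @param path YAML file path.
#' @return Validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$constraints)) {
    raw$constraints <- if (is.character(raw$constraints))
      read_constraints(raw$constraints)
    else lapply(raw$constraints, function(cn)
      physio_constraint(cn$predictor, c(cn$opt_lo, cn$opt_hi), cn$hard_limit,
                        cn$limit_side %||% "upper", cn$edges %||% "free_within"))
  }
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param cfg A `run_config` candidate.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  if (cfg$replicates < 1) errs <- c(errs, "replicates must be >= 1")
  if (length(cfg$buffers_km) < 1 || any(diff(cfg$buffers_km) <= 0))
    errs <- c(errs, "buffers_km must be strictly increasing")
  if (!all(cfg$model_types %in% c("naive", "informed")))
    errs <- c(errs, "model_types must be among 'naive', 'informed'")
  if (!cfg$evaluate %in% c("none", "first"))
    errs <- c(errs, "evaluate must be 'none' or 'first'")
  mc <- utils::modifyList(list(n_iter = 5000, n_warmup = 4000), cfg$mcmc)
  if (mc$n_warmup >= mc$n_iter)
    errs <- c(errs, sprintf("n_warmup (%d) must be < n_iter (%d)",
                            mc$n_warmup, mc$n_iter))
  if (cfg$omission < 0 || cfg$omission >= 1)
    errs <- c(errs, "omission must lie in [0, 1)")
  if (cfg$thin_km <= 0) errs <- c(errs, "thin_km must be > 0")
  if (length(errs)) stopf("invalid configuration:\n- %s",
                          paste(errs, collapse = "\n- "))
  cfg
}

#' Run the full comparison experiment
#'
#' Simulate a landscape with known truth, prepare occurrences, then for every
#' (buffer x model type x replicate) draw a fresh pseudo-absence set, fit the
#' plateau model, project present and future suitability over the largest
#' buffer and binarize — finally computing the comparison analytics
#' (cross-buffer Jaccard stability, range expansion/contraction, paired
#' Wilcoxon contrasts, southern limits). Fully deterministic for a fixed
#' config: stage seeds are derived from the master seed.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional directory; when given, occurrences, binary maps,
#'   comparison tables and the manifest are written there.
#' @param quiet Suppress progress lines.
#' @return List with `manifest` (one row per fitted model), `comparison`
#'   (Jaccard/range-change/Wilcoxon/southern-limit tables), `evaluation`
#'   (per-fold Boyce, when requested), `vif`, `cleaning_log`, and the
#'   simulated inputs (`env`, `truth`, `occurrences`, `transform`).
#' @export
run_experiment <- function(cfg, out_dir = NULL, quiet = TRUE) {
  validate_config(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  # --- simulate ------------------------------------------------------------
  lcfg <- do.call(landscape_config,
                  utils::modifyList(list(seed = derive_seed(cfg$seed, 1L)),
                                    cfg$landscape))
  env <- simulate_landscape(lcfg)
  tr_global <- global_transform(env)
  truth <- default_true_response(tr_global)
  suit_true <- true_suitability(env, truth, tr_global)
  region <- NULL
  if (!is.null(cfg$truncation_temp))
    region <- !is.na(env$layers$temp_mean) &
      env$layers$temp_mean <= cfg$truncation_temp
  occ_raw <- sample_occurrences(suit_true, cfg$n_presences, cfg$bias_strength,
                                seed = derive_seed(cfg$seed, 2L), region = region)
  say("simulate: %d presences sampled", nrow(occ_raw))

  # --- prep ----------------------------------------------------------------
  occ <- clean_records(occ_raw, env)
  occ <- thin_records(occ, cfg$thin_km, seed = derive_seed(cfg$seed, 3L))
  areas <- lapply(cfg$buffers_km, function(r) buffer_area(occ, r, env))
  names(areas) <- as.character(cfg$buffers_km)
  largest <- areas[[length(areas)]]
  norm <- normalize_predictors(env, largest)
  env_norm <- norm$env
  env_future <- make_future(env, cfg$future$delta_temp %||% 2,
                            cfg$future$delta_range %||% 0,
                            seed = derive_seed(cfg$seed, 4L),
                            warming_sd = cfg$future$warming_sd %||% 0.3)
  env_future_norm <- normalize_stack(env_future, norm$transform)
  vif <- vif_check(env, largest, cfg$vif_threshold)
  say("prep: %d presences retained, largest buffer %d cells",
      nrow(occ), sum(largest$mask))

  # --- fit / project -------------------------------------------------------
  mcfg0 <- utils::modifyList(
    list(n_chains = 2, n_iter = 5000, n_warmup = 4000, init_jitter = 0),
    cfg$mcmc)
  preds <- names(env$layers)
  priors <- list()
  for (ty in cfg$model_types)
    priors[[ty]] <- build_prior(ty, preds, cfg$constraints, norm$transform)

  manifest <- list(); maps_now <- list(); maps_fut <- list()
  changes <- list(); eval_rows <- list()
  proj_cells <- stack_cells(env_norm, mask = largest$mask, complete_only = TRUE)
  for (bi in seq_along(cfg$buffers_km)) {
    b <- cfg$buffers_km[bi]
    for (ty in cfg$model_types) {
      ti <- match(ty, c("naive", "informed"))
      for (r in seq_len(cfg$replicates)) {
        fit_seed <- derive_seed(cfg$seed, 5L, bi, ti, r)
        pa <- draw_pseudo_absences(areas[[bi]], env, occ,
                                   seed = derive_seed(cfg$seed, 6L, bi, r))
        all_occ <- occurrence_set(rbind(occ[c("lon", "lat", "label", "row", "col")],
                                        pa[c("lon", "lat", "label", "row", "col")]))
        mf <- model_frame(all_occ, env_norm, preds)
        fit <- fit_mcmc(mf, priors[[ty]],
                        do.call(mcmc_config,
                                utils::modifyList(mcfg0, list(seed = fit_seed))))
        pres_mf <- model_frame(occ, env_norm, preds)
        pres_suit <- posterior_predict(fit, pres_mf$X)$mean
        sm_now <- project_map(fit, env_norm, largest$mask)
        sm_fut <- project_map(fit, env_future_norm, largest$mask)
        bm_now <- binarize(sm_now, pres_suit, cfg$omission)
        bm_fut <- binarize(sm_fut, pres_suit, cfg$omission)
        key <- sprintf("%s_%d_r%02d", ty, b, r)
        maps_now[[key]] <- bm_now; maps_fut[[key]] <- bm_fut
        rc <- range_change(bm_now, bm_fut)
        changes[[key]] <- data.frame(buffer_km = b, type = ty, replicate = r,
                                     expansion = rc[["expansion"]],
                                     contraction = rc[["contraction"]],
                                     southern_limit = southern_limit(bm_now),
                                     threshold = bm_now$threshold)
        manifest[[key]] <- data.frame(
          stage = "fit", buffer_km = b, type = ty, replicate = r,
          seed = fit_seed, n_data = length(mf$y),
          n_draws = length(fit$chains) * nrow(fit$chains[[1]]),
          max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE), artifact = key)
        if (cfg$evaluate == "first" && r == 1L) {
          folds <- spatial_block_folds(all_occ, seed = derive_seed(cfg$seed, 7L, bi, ti))
          bv <- cross_validate(all_occ, env_norm, areas[[bi]], priors[[ty]],
                               do.call(mcmc_config,
                                       utils::modifyList(mcfg0, list(seed = fit_seed))),
                               folds)
          eval_rows[[key]] <- data.frame(buffer_km = b, type = ty, fold = seq_along(bv),
                                         boyce = bv)
        }
        say("fit: buffer %d km, %s, replicate %d (%.1fs elapsed)",
            b, ty, r, as.numeric(difftime(Sys.time(), t0, units = "secs")))
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  changes <- do.call(rbind, changes)
  rownames(changes) <- NULL

  # --- compare -------------------------------------------------------------
  comparison <- compare_maps(maps_now, changes, cfg)
  manifest_hash <- rlang::hash(list(unclass_deep(cfg), manifest, changes))

  res <- list(manifest = manifest, manifest_hash = manifest_hash,
              comparison = comparison,
              evaluation = if (length(eval_rows)) do.call(rbind, eval_rows),
              vif = vif, cleaning_log = occ_meta(occ)$cleaning_log,
              env = env, truth = truth, occurrences = occ,
              areas = areas, transform = norm$transform,
              maps_present = maps_now, maps_future = maps_fut, config = cfg)
  if (!is.null(out_dir)) write_artifacts(res, out_dir)
  res
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

# cross-buffer Jaccard + contrasts from the per-replicate binary maps
compare_maps <- function(maps_now, changes, cfg) {
  jac <- list()
  buffers <- cfg$buffers_km
  for (ty in cfg$model_types) {
    for (i in seq_along(buffers)) for (j in seq_along(buffers)) {
      if (i >= j) next
      a <- maps_now[sprintf("%s_%d_r%02d", ty, buffers[i], seq_len(cfg$replicates))]
      b <- maps_now[sprintf("%s_%d_r%02d", ty, buffers[j], seq_len(cfg$replicates))]
      jac[[sprintf("%s_%d_vs_%d", ty, buffers[i], buffers[j])]] <-
        pairwise_jaccard(unname(a), unname(b))
    }
  }
  wilcox <- list()
  if (all(c("naive", "informed") %in% cfg$model_types)) {
    for (i in seq_along(buffers)) for (j in seq_along(buffers)) {
      if (i >= j) next
      nj <- jac[[sprintf("naive_%d_vs_%d", buffers[i], buffers[j])]]$matrix
      ij <- jac[[sprintf("informed_%d_vs_%d", buffers[i], buffers[j])]]$matrix
      wilcox[[sprintf("jaccard_%d_vs_%d", buffers[i], buffers[j])]] <-
        tryCatch(paired_wilcoxon(as.vector(ij), as.vector(nj), "greater"),
                 error = function(e) NULL)
    }
    if (cfg$replicates >= 3) {
      for (b in buffers) {
        nv <- changes[changes$type == "naive" & changes$buffer_km == b, ]
        iv <- changes[changes$type == "informed" & changes$buffer_km == b, ]
        wilcox[[sprintf("expansion_%d", b)]] <-
          tryCatch(paired_wilcoxon(nv$expansion, iv$expansion), error = function(e) NULL)
        wilcox[[sprintf("contraction_%d", b)]] <-
          tryCatch(paired_wilcoxon(nv$contraction, iv$contraction), error = function(e) NULL)
      }
    }
  }
  jac_summary <- do.call(rbind, lapply(names(jac), function(nm)
    data.frame(contrast = nm, mean = jac[[nm]]$mean, se = jac[[nm]]$se,
               n_pairs = length(jac[[nm]]$matrix))))
  list(jaccard = jac, jaccard_summary = jac_summary,
       range_change = changes, wilcoxon = wilcox)
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_occurrences(res$occurrences, file.path(out_dir, "occurrences.csv"))
  for (nm in names(res$maps_present))
    write_binary_map(res$maps_present[[nm]], file.path(out_dir, paste0("map_now_", nm)))
  for (nm in names(res$maps_future))
    write_binary_map(res$maps_future[[nm]], file.path(out_dir, paste0("map_future_", nm)))
  write.csv(res$comparison$range_change, file.path(out_dir, "range_change.csv"),
            row.names = FALSE)
  write.csv(res$comparison$jaccard_summary, file.path(out_dir, "jaccard_summary.csv"),
            row.names = FALSE)
  write.csv(res$manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(hash = res$manifest_hash,
                            config = unclass_deep(res$config),
                            vif = res$vif,
                            cleaning_log = res$cleaning_log),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
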