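test_that("trapezoid penalty arithmetic and plateau interior", {
  expect_equal(plateau_response(0.2, c1 = 0.3, c2 = 0.6, b1 = 10, b2 = 20), -1.0)
  expect_equal(plateau_response(0.7, c1 = 0.3, c2 = 0.6, b1 = 10, b2 = 20), -2.0)
  x <- seq(0.3, 0.6, length.out = 11)
  expect_true(all(plateau_response(x, 0.3, 0.6, 10, 20) == 0))
  # continuous, piecewise linear, always <= 0
  xs <- seq(-0.5, 1.5, by = 0.01)
  f <- plateau_response(xs, 0.3, 0.6, 10, 20)
  expect_true(all(f <= 0))
  expect_true(all(abs(diff(f, differences = 2)) < 0.21))  # two slope breaks only
  expect_error(plateau_response(0.5, 0.7, 0.3, 1, 1), "c1")
  expect_error(plateau_response(0.5, 0.3, 0.7, -1, 1), "slopes")
})

test_that("presence probability: apex at plateau, decay past edges, monotonicity", {
  pars <- plateau_params(0, data.frame(predictor = c("a", "b"),
                                       c1 = c(0.2, 0.3), c2 = c(0.7, 0.6),
                                       b1 = c(5, 8), b2 = c(9, 30)))
  expect_equal(presence_probability(data.frame(a = 0.5, b = 0.5), pars), 0.5)
  expect_lt(presence_probability(data.frame(a = 30, b = 0.5), pars), 1e-12)
  # farther past c2 is strictly less suitable
  p1 <- presence_probability(data.frame(a = 0.8, b = 0.5), pars)
  p2 <- presence_probability(data.frame(a = 0.9, b = 0.5), pars)
  expect_lt(p2, p1)
  expect_error(presence_probability(data.frame(a = 0.5), pars), "missing")
})

test_that("log-likelihood matches direct summation and is permutation-invariant", {
  pars <- recovery_truth()
  set.seed(5)
  X <- as.data.frame(matrix(runif(30), 10, 3))
  names(X) <- pars$params$predictor
  y <- rbinom(10, 1, 0.5)
  p <- presence_probability(X, pars)
  oracle <- sum(log(ifelse(y == 1, p, 1 - p)))
  expect_equal(log_likelihood(X, y, pars), oracle, tolerance = 1e-12)
  perm <- sample(10)
  expect_equal(log_likelihood(X[perm, ], y[perm], pars),
               log_likelihood(X, y, pars), tolerance = 1e-12)
  # no-penalty model at beta0 = 0: n * log(0.5)
  flat <- plateau_params(0, data.frame(predictor = "a", c1 = -1e9, c2 = 1e9,
                                       b1 = 0, b2 = 0))
  expect_equal(log_likelihood(data.frame(a = runif(7)), rep(1, 7), flat),
               7 * log(0.5))
  # C++ likelihood used by the sampler agrees with the R implementation
  slot_par <- c(t(as.matrix(pars$params[c("c1", "c2", "b1", "b2")])), pars$intercept)
  expect_equal(plateauSDM:::plateau_loglik_cpp(as.matrix(X), y, slot_par),
               log_likelihood(X, y, pars), tolerance = 1e-9)
})

test_that("naive priors span the normalized range; informed priors encode the constraints", {
  P <- prepared_landscape()
  tr <- P$transform_area
  naive <- build_prior("naive", names(P$env$layers))
  tab <- naive$table
  edges <- tab[tab$param %in% c("c1", "c2"), ]
  expect_true(all(edges$lower == 0 & edges$upper == 1))
  expect_true(all(tab$dist[tab$param %in% c("b1", "b2")] == "halfnorm"))

  informed <- build_prior("informed", names(P$env$layers), transform = tr)
  it <- informed$table
  t15 <- normalize_values(15, tr, "temp_mean")
  t18 <- normalize_values(18, tr, "temp_mean")
  tc <- it[it$predictor == "temp_mean" & it$param == "c2", ]
  expect_equal(c(tc$lower, tc$upper), c(t15, t18))
  expect_equal(it$role[it$predictor == "temp_mean" & it$param == "b2"], "linked")
  dep <- it[it$predictor %in% "depth", ]
  expect_equal(dep$role[dep$param %in% c("c1", "c2")], c("fixed", "fixed"))
  expect_equal(dep$value[dep$param == "c2"], normalize_values(40, tr, "depth"))
  # salinity, current, distance to shore keep vague priors in informed mode
  for (nm in c("salinity", "current", "dist_shore"))
    expect_true(all(it$role[it$predictor %in% nm] == "free"))
  expect_error(build_prior("informed", c("salinity"),
                           constraints = default_constraints(), transform = tr),
               "unknown predictor")
})

test_that("forward prior draws always satisfy the plateau constraints", {
  P <- prepared_landscape()
  for (mode in c("naive", "informed")) {
    prior <- build_prior(mode, names(P$env$layers), transform = P$transform_area)
    draws <- prior_sample(prior, 100, seed = 3)
    for (d in draws) {
      expect_true(all(d$params$c1 <= d$params$c2))
      expect_true(all(d$params$b1 >= 0 & d$params$b2 >= 0))
    }
  }
})

test_that("the shipped constraint table parses to the default constraints", {
  path <- system.file("extdata", "physio_constraints.csv", package = "plateauSDM")
  cons <- read_constraints(path)
  expect_length(cons, 2L)
  expect_equal(cons[[1]]$predictor, "temp_mean")
  expect_equal(c(cons[[1]]$opt_lo, cons[[1]]$opt_hi, cons[[1]]$hard_limit),
               c(15, 18, 26))
  expect_equal(cons[[2]]$hard_limit, 200)
})

test_that("default MCMC schedule retains 1000 draws per chain and is deterministic", {
  S <- small_tabular_fit()
  fit <- S$fit
  expect_length(fit$chains, 2L)
  cfg <- fit$config
  expect_equal(nrow(fit$chains[[1]]), cfg$n_iter - cfg$n_warmup)
  refit <- fit_mcmc(S$data, S$prior,
                    mcmc_config(n_iter = 1200, n_warmup = 900, seed = 4))
  expect_identical(refit$chains, fit$chains)
  # every retained draw satisfies the parameter constraints
  d <- plateauSDM:::posterior_draws(fit)
  for (nm in S$truth$params$predictor) {
    expect_true(all(d[, paste0(nm, ".c1")] <= d[, paste0(nm, ".c2")]))
    expect_true(all(d[, paste0(nm, ".b1")] >= 0))
    expect_true(all(d[, paste0(nm, ".b2")] >= 0))
  }
  expect_error(fit_mcmc(list(X = S$data$X, y = rep(1, 400)), S$prior),
               "both labels")
  expect_error(mcmc_config(n_iter = 100, n_warmup = 100), "n_warmup")
  expect_error(mcmc_config(n_chains = 1), "n_chains")
})

test_that("short-run posterior recovers the teacher's plateau edges", {
  S <- small_tabular_fit()
  s <- summary(S$fit)
  for (j in seq_len(3)) {
    nm <- S$truth$params$predictor[j]
    for (e in c("c1", "c2")) {
      row <- s[s$parameter == paste0(nm, ".", e), ]
      expect_lt(abs(row$mean - S$truth$params[[e]][j]), 0.15)
    }
  }
})

test_that("informed posteriors respect the thermal window and absence floor", {
  P <- prepared_landscape()
  fit <- landscape_fit("informed")
  tr <- P$transform_area
  d <- plateauSDM:::posterior_draws(fit)
  t15 <- normalize_values(15, tr, "temp_mean")
  t18 <- normalize_values(18, tr, "temp_mean")
  expect_true(all(d[, "temp_mean.c2"] >= t15 - 1e-12 &
                  d[, "temp_mean.c2"] <= t18 + 1e-12))
  expect_true(all(d[, "temp_mean.c1"] >= t15 - 1e-12))
  expect_true(all(d[, "temp_mean.b2"] > 0))       # linked slope assembled
  # with all other predictors on-plateau, response at 26 degC <= 0.05
  x26 <- normalize_values(26, tr, "temp_mean")
  on_plateau <- data.frame(
    depth = mean(d[, "depth.c1"]), dist_shore = 0.5, temp_mean = x26,
    temp_range = 0.5, salinity = 0.5, current = 0.5)
  pd <- data.frame(lapply(on_plateau, rep, 2))
  # set nuisance predictors inside each draw's plateau: use per-draw evaluation
  probs <- vapply(seq_len(nrow(d)), function(i) {
    pars <- plateauSDM:::assemble_to_params(d[i, ], fit$predictors)
    x <- as.data.frame(as.list(setNames(
      pmin(pmax(0.5, pars$params$c1), pars$params$c2), fit$predictors)))
    x$temp_mean <- x26
    presence_probability(x, pars)
  }, numeric(1))
  expect_lte(mean(probs), 0.05)
})

test_that("posterior prediction equals the brute-force draw average", {
  S <- small_tabular_fit()
  fit <- S$fit
  sub <- lapply(fit$chains, function(ch) ch[1:25, , drop = FALSE])
  post <- fake_posterior(sub, fit$predictors, fit$free_names, fit$prior)
  set.seed(2)
  X <- as.data.frame(matrix(runif(15), 5, 3))
  names(X) <- fit$predictors
  got <- posterior_predict(post, X)
  d <- do.call(rbind, sub)
  oracle <- sapply(seq_len(5), function(i) {
    mean(vapply(seq_len(nrow(d)), function(k) {
      pars <- plateauSDM:::assemble_to_params(d[k, ], fit$predictors)
      presence_probability(X[i, , drop = FALSE], pars)
    }, numeric(1)))
  })
  expect_equal(got$mean, oracle, tolerance = 1e-10)
  expect_true(all(got$lower <= got$mean & got$mean <= got$upper))
  # degenerate posterior: all draws equal -> zero-width interval
  one <- d[7, , drop = FALSE]
  deg <- fake_posterior(list(one[rep(1, 10), ], one[rep(1, 10), ]),
                        fit$predictors, fit$free_names, fit$prior)
  gd <- posterior_predict(deg, X)
  expect_equal(gd$lower, gd$mean)
  expect_equal(gd$upper, gd$mean)
})

test_that("split R-hat and ESS behave on engineered chains", {
  set.seed(8)
  good <- list(matrix(rnorm(600), ncol = 1, dimnames = list(NULL, "intercept")),
               matrix(rnorm(600), ncol = 1, dimnames = list(NULL, "intercept")))
  post <- fake_posterior(good, predictors = character(0))
  dg <- convergence_diagnostics(post, warn = FALSE)
  expect_lt(abs(dg$rhat - 1), 0.05)
  expect_lte(dg$ess, 1200)
  bad <- list(good[[1]], good[[2]] + 10)
  postb <- fake_posterior(bad, predictors = character(0))
  expect_warning(db <- convergence_diagnostics(postb), "R-hat")
  expect_gt(db$rhat, 1.5)
  single <- fake_posterior(good[1], predictors = character(0))
  expect_error(convergence_diagnostics(single), "chains")
})

test_that("posteriors round-trip to CSV with a JSON sidecar", {
  fit <- small_tabular_fit()$fit
  prefix <- tempfile("post")
  write_posterior(fit, prefix)
  d <- read.csv(paste0(prefix, ".csv"))
  expect_equal(nrow(d), 2 * nrow(fit$chains[[1]]))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(meta$prior_mode, "naive")
  expect_equal(meta$config$n_iter, 1200)
})
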