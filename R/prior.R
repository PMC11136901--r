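#' Physiological constraint for one predictor
#'
#' Encodes laboratory- or field-derived tolerance knowledge in *physical*
#' units: an optimal range (the plateau) and a hard limit beyond which the
#' species is effectively absent. For the Japanese sea cucumber analogue the
#' shipped defaults are an optimal temperature of 15-18 degC with a 26 degC
#' upper limit, and an optimal depth of 0-40 m with a 200 m limit.
#'
#' @param predictor Layer name the constraint applies to.
#' @param optimal Length-2 numeric, the optimal range (physical units).
#' @param hard_limit Hard tolerance limit (physical units), or `NA` when
#'   `limit_side = "none"`.
#' @param limit_side One of `"upper"`, `"lower"`, `"none"`.
#' @param edges `"free_within"`: plateau edges get uniform priors over the
#'   normalized optimal range; `"fixed"`: edges are pinned to it.
#' @return Object of class `physio_constraint` (a one-row data.frame).
#' @export
physio_constraint <- function(predictor, optimal, hard_limit = NA,
                              limit_side = c("upper", "lower", "none"),
                              edges = c("free_within", "fixed")) {
  limit_side <- match.arg(limit_side)
  edges <- match.arg(edges)
  if (limit_side != "none") {
    if (is.na(hard_limit)) stopf("hard_limit required for limit_side '%s'", limit_side)
    if (limit_side == "upper" && hard_limit <= optimal[2])
      stopf("upper hard_limit must exceed the optimal range")
    if (limit_side == "lower" && hard_limit >= optimal[1])
      stopf("lower hard_limit must fall below the optimal range")
  }
  structure(data.frame(predictor = predictor, opt_lo = optimal[1],
                       opt_hi = optimal[2], hard_limit = hard_limit,
                       limit_side = limit_side, edges = edges,
                       stringsAsFactors = FALSE),
            class = c("physio_constraint", "data.frame"))
}

#' Read a physiological-constraint table from CSV
#'
#' Columns: `predictor, opt_lo, opt_hi, hard_limit, limit_side, edges`
#' (physical units). The package ships the sea-cucumber-analogue table at
#' `system.file("extdata", "physio_constraints.csv", package = "plateauSDM")`.
#'
#' @param path CSV path.
#' @return List of [physio_constraint()] rows.
#' @export
read_constraints <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    physio_constraint(tab$predictor[i], c(tab$opt_lo[i], tab$opt_hi[i]),
                      tab$hard_limit[i], tab$limit_side[i], tab$edges[i]))
}

#' Default physiological constraints (sea-cucumber analogue)
#'
#' Annual mean temperature: optimum 15-18 degC, upper limit 26 degC, plateau
#' edges free within the optimum; depth: optimum 0-40 m pinned as the
#' plateau, hard limit 200 m. No constraints on temperature range, salinity,
#' current velocity or distance to shore.
#'
#' @return List of [physio_constraint()] objects.
#' @export
default_constraints <- function() {
  list(physio_constraint("temp_mean", c(15, 18), 26, "upper", "free_within"),
       physio_constraint("depth", c(0, 40), 200, "upper", "fixed"))
}

#' Build the prior specification for a plateau model
#'
#' `mode = "naive"`: vague priors for every predictor — plateau edges are
#' the order statistics of two independent Uniform(0, 1) draws, slopes are
#' half-Normal(sd 10), the intercept is Normal(0, sd 5).
#'
#' `mode = "informed"`: predictors named in `constraints` get their plateau
#' restricted to the normalized image of the optimal range (uniform within
#' it, or pinned, per the constraint's `edges`), and the slope on the limit
#' side is *deterministically linked* so that the response at the hard limit
#' equals the "effectively absent" floor: on the upper side
#' `b2 = (beta0 - L) / (x_limit - c2)` with `L = qlogis(floor)`.
#' Unconstrained predictors keep the naive settings.
#'
#' @param mode `"naive"` or `"informed"`.
#' @param predictors Character vector of modelled predictors, in model-matrix
#'   column order.
#' @param constraints List of [physio_constraint()] (physical units); used
#'   only in informed mode.
#' @param transform `norm_transform` from [normalize_predictors()]; maps the
#'   physical constants onto the shared normalized scale.
#' @param floor Probability defining "effectively absent" at the hard limit
#'   (default 0.01); `L = qlogis(floor)`.
#' @return Object of class `prior_spec`.
#' @export
build_prior <- function(mode = c("naive", "informed"), predictors,
                        constraints = default_constraints(),
                        transform = NULL, floor = 0.01) {
  mode <- match.arg(mode)
  rows <- list()
  add <- function(predictor, param, role, dist = NA, p1 = NA, p2 = NA,
                  lower = NA, upper = NA, value = NA, limit_x = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      predictor = predictor, param = param, role = role, dist = dist,
      p1 = p1, p2 = p2, lower = lower, upper = upper, value = value,
      limit_x = limit_x, stringsAsFactors = FALSE)
  }
  naive_pred <- function(nm) {
    add(nm, "c1", "free", "unif", lower = 0, upper = 1)
    add(nm, "c2", "free", "unif", lower = 0, upper = 1)
    add(nm, "b1", "free", "halfnorm", p1 = 10, lower = 0, upper = Inf)
    add(nm, "b2", "free", "halfnorm", p1 = 10, lower = 0, upper = Inf)
  }

  cons_map <- list()
  if (mode == "informed") {
    for (cn in constraints) cons_map[[cn$predictor]] <- cn
    unknown <- setdiff(names(cons_map), predictors)
    if (length(unknown))
      stopf("constraint references unknown predictor(s): %s",
            paste(unknown, collapse = ", "))
    if (is.null(transform))
      stopf("informed priors need the normalization transform")
    missing_tr <- setdiff(names(cons_map), transform$layer)
    if (length(missing_tr))
      stopf("transform does not cover constrained predictor(s): %s",
            paste(missing_tr, collapse = ", "))
  }

  for (nm in predictors) {
    cn <- cons_map[[nm]]
    if (is.null(cn)) { naive_pred(nm); next }
    lo <- normalize_values(cn$opt_lo, transform, nm)
    hi <- normalize_values(cn$opt_hi, transform, nm)
    if (cn$edges == "fixed") {
      add(nm, "c1", "fixed", value = lo)
      add(nm, "c2", "fixed", value = hi)
    } else {
      add(nm, "c1", "free", "unif", lower = lo, upper = hi)
      add(nm, "c2", "free", "unif", lower = lo, upper = hi)
    }
    if (cn$limit_side == "lower") {
      xl <- normalize_values(cn$hard_limit, transform, nm)
      if (xl >= lo) stopf("'%s': normalized lower limit is not below the plateau", nm)
      add(nm, "b1", "linked", limit_x = xl)
    } else {
      add(nm, "b1", "free", "halfnorm", p1 = 10, lower = 0, upper = Inf)
    }
    if (cn$limit_side == "upper") {
      xl <- normalize_values(cn$hard_limit, transform, nm)
      if (xl <= hi) stopf("'%s': normalized upper limit is not above the plateau", nm)
      add(nm, "b2", "linked", limit_x = xl)
    } else {
      add(nm, "b2", "free", "halfnorm", p1 = 10, lower = 0, upper = Inf)
    }
  }
  add(NA_character_, "intercept", "free", "norm", p1 = 0, p2 = 5,
      lower = -Inf, upper = Inf)

  tab <- do.call(rbind, rows)
  free <- tab$role == "free"
  tab$theta_idx <- NA_integer_
  tab$theta_idx[free] <- seq_len(sum(free))
  structure(list(mode = mode, predictors = predictors, table = tab,
                 floor = floor, L = qlogis(floor), transform = transform),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> mode = %s, %d predictors, %d free parameters\n",
              x$mode, length(x$predictors), sum(x$table$role == "free")))
  print(x$table[c("predictor", "param", "role", "dist", "lower", "upper",
                  "value", "limit_x")], row.names = FALSE)
  invisible(x)
}

# central initial values on the prior scale (shared by both chains, as in
# the study's MCMC setup)
prior_inits <- function(prior) {
  tab <- prior$table[prior$table$role == "free", ]
  vapply(seq_len(nrow(tab)), function(i) {
    switch(tab$dist[i],
           unif = {
             mid <- (tab$lower[i] + tab$upper[i]) / 2
             span <- tab$upper[i] - tab$lower[i]
             # stagger c1 below c2 so the order constraint holds strictly
             if (tab$param[i] == "c1") mid - span / 6
             else if (tab$param[i] == "c2") mid + span / 6
             else mid
           },
           halfnorm = 0.5 * tab$p1[i],
           norm = tab$p1[i])
  }, numeric(1))
}

#' Forward draws from a prior specification
#'
#' Samples parameter sets from the prior (linked slopes computed from the
#' drawn intercept and edge). Used for prior predictive checks; every draw
#' satisfies the plateau-parameter constraints by construction.
#'
#' @param prior A `prior_spec` from [build_prior()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return List of [plateau_params()] objects.
#' @export
prior_sample <- function(prior, n = 1, seed = 1L) {
  set.seed(derive_seed(seed, 88L))
  tab <- prior$table
  lapply(seq_len(n), function(i) {
    vals <- setNames(numeric(nrow(tab)), paste(tab$predictor, tab$param))
    for (r in seq_len(nrow(tab))) {
      vals[r] <- switch(tab$role[r],
        fixed = tab$value[r],
        free = switch(tab$dist[r],
          unif = runif(1, tab$lower[r], tab$upper[r]),
          halfnorm = abs(rnorm(1, 0, tab$p1[r])),
          norm = rnorm(1, tab$p1[r], tab$p2[r])),
        linked = NA_real_)
    }
    # enforce the order-statistics reading of the edge priors: sort the pair
    for (nm in prior$predictors) {
      i1 <- which(tab$predictor == nm & tab$param == "c1")
      i2 <- which(tab$predictor == nm & tab$param == "c2")
      if (tab$role[i1] == "free" && tab$role[i2] == "free" &&
          vals[i1] > vals[i2]) vals[c(i1, i2)] <- vals[c(i2, i1)]
    }
    beta0 <- vals[tab$param == "intercept"]
    # intercept draws at or below the floor cannot support a linked slope;
    # resample the intercept above L in that rare case
    if (any(tab$role == "linked") && beta0 <= prior$L) {
      while (beta0 <= prior$L) beta0 <- rnorm(1, 0, 5)
      vals[tab$param == "intercept"] <- beta0
    }
    for (r in which(tab$role == "linked")) {
      edge_param <- if (tab$param[r] == "b2") "c2" else "c1"
      ei <- which(tab$predictor == tab$predictor[r] & tab$param == edge_param)
      gap <- if (tab$param[r] == "b2") tab$limit_x[r] - vals[ei]
             else vals[ei] - tab$limit_x[r]
      vals[r] <- (beta0 - prior$L) / gap
    }
    pm <- data.frame(predictor = prior$predictors,
                     c1 = vals[tab$param == "c1"], c2 = vals[tab$param == "c2"],
                     b1 = vals[tab$param == "b1"], b2 = vals[tab$param == "b2"])
    plateau_params(unname(beta0), pm)
  })
}
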