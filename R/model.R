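# Bayesian hierarchical spatio-temporal Poisson model (BYM convolution +
# RW1 year effect), fitted by Metropolis-within-Gibbs MCMC.
#
# Likelihood and priors, for one (site, outcome, stratum) query:
#   y_{iat} ~ Poisson(n_{iat} * lambda_{iat})
#   log lambda_{iat} = mu + alpha_a + u_i + v_i + gamma_t
#   u  ~ ICAR:  p(u | tau_u) propto tau_u^{(I-C)/2} exp(-tau_u/2 sum_{i~j} (u_i-u_j)^2)
#   v_i ~ N(0, 1/tau_v);  gamma ~ RW1(tau_g);  mu, alpha_a ~ N(0, fe_sd^2)
#   tau_* ~ Gamma(shape a0, rate b0)
# Identifiability: sum(alpha) = 0, sum(gamma) = 0, sum(u) = 0 per graph
# component, enforced by re-centering after each block sweep (mu absorbs the
# mean).  I = number of areas, C = number of graph components (the ICAR rank
# deficiency), T = number of years.

#' Sampler and prior settings
#'
#' @param chains number of independent chains.
#' @param iterations MCMC iterations per chain (including burn-in).
#' @param burn_in iterations discarded; must be `< iterations`.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param hyper_shape,hyper_rate Gamma(shape, rate) hyperprior on each
#'   precision; the weakly-informative default Gamma(1, 0.01) keeps the
#'   posterior proper despite the impropriety of the ICAR prior.
#' @param fe_sd prior SD of the fixed effects `mu` and `alpha`.
#' @param proposal initial random-walk proposal SDs per block, named
#'   `mu, alpha, u, v, gamma`; adapted toward 0.44 acceptance during burn-in
#'   and frozen afterwards.
#' @param use_spatial,use_temporal switch the structured spatial / temporal
#'   terms on or off.
#' @param adapt adapt proposal SDs during burn-in.
#' @param seed integer master seed; chains use [split_seed()] sub-streams.
#' @return a `model_spec` list.
#' @export
model_spec <- function(chains = 2L, iterations = 11000L, burn_in = 1000L,
                       thin = 10L, hyper_shape = 1, hyper_rate = 0.01,
                       fe_sd = 10,
                       proposal = c(mu = 0.1, alpha = 0.1, u = 0.1, v = 0.1,
                                    gamma = 0.1),
                       use_spatial = TRUE, use_temporal = TRUE,
                       adapt = TRUE, seed = 1L) {
  stopifnot(burn_in < iterations, thin >= 1, hyper_shape > 0, hyper_rate > 0,
            fe_sd > 0,
            all(c("mu", "alpha", "u", "v", "gamma") %in% names(proposal)))
  structure(as.list(environment()), class = "model_spec")
}

#' Prepare registry data for one model fit
#'
#' Restricts the registry to one site/outcome, resolves the stratum query
#' (pooling over `"all"` strata by summing events and person-years), and,
#' for a year-range query, collapses years — the fit then has no temporal
#' term.  Cells with zero person-years are dropped: they contribute nothing
#' to the likelihood.
#'
#' @param registry registry data frame (see [simulate_counts()]).
#' @param graph an [area_graph()]; every registry area must appear in it.
#' @param query a normalized query from [validate_query()], or a list with
#'   elements `site`, `outcome`, `sex`, `race` and optional `year_range`
#'   (length-2 integer vector that pools those years into one period).
#' @return a `bym_data` list with parallel vectors `y`, `n`, `area`, `age`,
#'   `year_idx` plus the label dictionaries.
#' @export
build_model_data <- function(registry, graph, query) {
  validate_registry(registry)
  if (!all(registry$area_id %in% graph$area_ids)) {
    bad <- setdiff(unique(registry$area_id), graph$area_ids)
    ar_stop("registry areas missing from geography: ",
            paste(head(bad, 5L), collapse = ", "))
  }
  d <- registry[registry$site == query$site & registry$outcome == query$outcome, ]
  if (!identical(query$sex %||% "all", "all")) d <- d[d$sex == query$sex, ]
  if (!identical(query$race %||% "all", "all")) d <- d[d$race == query$race, ]
  collapse <- !is.null(query$year_range)
  if (collapse) {
    yr <- range(as.integer(query$year_range))
    d <- d[d$year >= yr[1L] & d$year <= yr[2L], ]
  }
  if (nrow(d) == 0L) ar_stop("no registry cells match the query")
  dt <- data.table::as.data.table(d)
  if (collapse) dt$year <- -1L  # single pooled period
  agg <- dt[, list(events = sum(events), person_years = sum(person_years)),
            by = c("area_id", "age_group", "year")]
  agg <- agg[agg$person_years > 0, ]
  if (nrow(agg) == 0L) ar_stop("no population at risk for the query")
  age_groups <- sort(unique(d$age_group))
  years <- if (collapse) -1L else sort(unique(agg$year))
  structure(list(
    y = as.integer(agg$events),
    n = as.numeric(agg$person_years),
    area = match(agg$area_id, graph$area_ids),
    age = match(agg$age_group, age_groups),
    year_idx = match(agg$year, years),
    area_ids = graph$area_ids,
    age_groups = age_groups,
    years = years,
    collapse_years = collapse,
    query = query
  ), class = "bym_data")
}

#' Construct a model state
#'
#' @param mu global intercept (log-rate scale).
#' @param alpha age effects, sum-to-zero.
#' @param u spatially structured area effects, sum-to-zero per component.
#' @param v unstructured area effects.
#' @param gamma year effects, sum-to-zero.
#' @param tau_u,tau_v,tau_g precisions, strictly positive.
#' @return a `model_state` list.
#' @export
model_state <- function(mu, alpha, u, v, gamma, tau_u, tau_v, tau_g) {
  structure(list(mu = mu, alpha = alpha, u = u, v = v, gamma = gamma,
                 tau_u = tau_u, tau_v = tau_v, tau_g = tau_g),
            class = "model_state")
}

#' @keywords internal
check_state <- function(state, graph, data, tol = 1e-8) {
  if (!all(c(state$tau_u, state$tau_v, state$tau_g) > 0)) {
    ar_stop("precisions must be strictly positive")
  }
  if (length(state$alpha) > 1L && !ar_near(sum(state$alpha), 0, tol)) {
    ar_stop("alpha violates the sum-to-zero constraint")
  }
  if (length(state$gamma) > 1L && !ar_near(sum(state$gamma), 0, tol)) {
    ar_stop("gamma violates the sum-to-zero constraint")
  }
  for (cid in seq_len(max(graph$component))) {
    if (!ar_near(sum(state$u[graph$component == cid]), 0, tol)) {
      ar_stop("u violates the per-component sum-to-zero constraint")
    }
  }
  invisible(TRUE)
}

#' Unnormalized log posterior density
#'
#' The exact target the sampler explores: Poisson log likelihood over cells
#' with positive exposure, the rank-adjusted ICAR kernel, Gaussian
#' unstructured and random-walk terms, Normal priors on the fixed effects and
#' Gamma priors on the precisions.  Normalizing constants that depend only on
#' data are included (full `dpois` mass), so values are comparable across
#' states but not across data sets.
#'
#' @param state a [model_state()] satisfying the sum-to-zero invariants (the
#'   function rejects violating states).
#' @param data a `bym_data` object from [build_model_data()].
#' @param graph the matching [area_graph()].
#' @param spec a [model_spec()].
#' @return scalar log density.
#' @export
log_posterior <- function(state, data, graph, spec) {
  check_state(state, graph, data)
  I <- n_areas(graph)
  C <- max(graph$component)
  T <- length(data$years)
  eta <- state$mu + state$alpha[data$age] + state$u[data$area] +
    state$v[data$area] + state$gamma[data$year_idx]
  if (any(!is.finite(eta))) ar_stop("non-finite linear predictor")
  lp <- sum(dpois(data$y, data$n * exp(eta), log = TRUE))
  qf <- 0
  if (nrow(graph$edges)) {
    du <- state$u[graph$edges[, 1L]] - state$u[graph$edges[, 2L]]
    qf <- sum(du^2)
  }
  lp <- lp + 0.5 * (I - C) * log(state$tau_u) - 0.5 * state$tau_u * qf
  lp <- lp + sum(dnorm(state$v, 0, 1 / sqrt(state$tau_v), log = TRUE))
  temporal <- spec$use_temporal && T > 1L && !data$collapse_years
  if (temporal) {
    dg <- diff(state$gamma)
    lp <- lp + 0.5 * (T - 1) * log(state$tau_g) - 0.5 * state$tau_g * sum(dg^2)
  }
  lp <- lp + dnorm(state$mu, 0, spec$fe_sd, log = TRUE) +
    sum(dnorm(state$alpha, 0, spec$fe_sd, log = TRUE))
  lp <- lp + dgamma(state$tau_u, spec$hyper_shape, rate = spec$hyper_rate, log = TRUE) +
    dgamma(state$tau_v, spec$hyper_shape, rate = spec$hyper_rate, log = TRUE)
  if (temporal) {
    lp <- lp + dgamma(state$tau_g, spec$hyper_shape, rate = spec$hyper_rate, log = TRUE)
  }
  lp
}

#' Conjugate posterior parameters of the precisions
#'
#' Given the current effects, each precision has a Gamma full conditional:
#' `tau_u ~ Gamma(a0 + (I - C)/2, b0 + Q_u/2)` with `Q_u` the ICAR quadratic
#' form over edges, `tau_v ~ Gamma(a0 + I/2, b0 + sum(v^2)/2)`, and
#' `tau_g ~ Gamma(a0 + (T - 1)/2, b0 + sum(diff(gamma)^2)/2)`.
#'
#' @inheritParams log_posterior
#' @return list of `(shape, rate)` pairs for `tau_u`, `tau_v`, `tau_g`.
#' @export
precision_posteriors <- function(state, data, graph, spec) {
  I <- n_areas(graph)
  C <- max(graph$component)
  T <- length(data$years)
  qf <- 0
  if (nrow(graph$edges)) {
    du <- state$u[graph$edges[, 1L]] - state$u[graph$edges[, 2L]]
    qf <- sum(du^2)
  }
  list(
    tau_u = c(shape = spec$hyper_shape + 0.5 * (I - C),
              rate = spec$hyper_rate + 0.5 * qf),
    tau_v = c(shape = spec$hyper_shape + 0.5 * I,
              rate = spec$hyper_rate + 0.5 * sum(state$v^2)),
    tau_g = c(shape = spec$hyper_shape + 0.5 * max(T - 1L, 0L),
              rate = spec$hyper_rate + 0.5 * sum(diff(state$gamma)^2))
  )
}

#' One Gibbs update of the precision parameters
#'
#' @inheritParams log_posterior
#' @return the state with freshly drawn `tau_u`, `tau_v`, `tau_g`.
#' @export
gibbs_update_precisions <- function(state, data, graph, spec) {
  check_state(state, graph, data)
  pp <- precision_posteriors(state, data, graph, spec)
  state$tau_u <- rgamma(1L, pp$tau_u["shape"], rate = pp$tau_u["rate"])
  state$tau_v <- rgamma(1L, pp$tau_v["shape"], rate = pp$tau_v["rate"])
  if (length(data$years) > 1L && spec$use_temporal && !data$collapse_years) {
    state$tau_g <- rgamma(1L, pp$tau_g["shape"], rate = pp$tau_g["rate"])
  }
  state
}

#' One (or more) Metropolis sweeps over all effect blocks
#'
#' Component-wise Gaussian random-walk Metropolis updates of `mu`, each
#' `alpha_a`, each `u_i`, each `v_i` and each `gamma_t`, using the exact full
#' conditionals of the model.  Constrained blocks are re-centered after their
#' sweep unless `recenter = FALSE` (useful for stationarity checks on an
#' unconstrained coordinate).  Precisions are left untouched; see
#' [gibbs_update_precisions()].
#'
#' @inheritParams log_posterior
#' @param sweeps number of full sweeps to run.
#' @param prop_sd named proposal SDs (`mu, alpha, u, v, gamma`); defaults to
#'   `spec$proposal`.  A block with SD 0 is proposed in place and therefore
#'   never moves.
#' @param recenter enforce the sum-to-zero constraints after each sweep.
#' @param keep_draws if `TRUE`, also return every swept state (one row per
#'   sweep) for diagnostic use.
#' @return the updated [model_state()]; with `keep_draws = TRUE` a list
#'   `list(state, draws)`.
#' @export
metropolis_sweep <- function(state, data, graph, spec, sweeps = 1L,
                             prop_sd = NULL, recenter = TRUE,
                             keep_draws = FALSE) {
  if (recenter) check_state(state, graph, data)
  prop <- if (is.null(prop_sd)) spec$proposal else prop_sd
  res <- cpp_bym_chain(
    y = data$y, n = data$n,
    area = data$area - 1L, age = data$age - 1L, yr = data$year_idx - 1L,
    I = n_areas(graph), A = length(data$age_groups), T = length(data$years),
    nbr0 = lapply(graph$nbr, function(x) as.integer(x - 1L)),
    edges0 = matrix(as.integer(graph$edges - 1L), ncol = 2L),
    comp0 = as.integer(graph$component - 1L), C = max(graph$component),
    init = unclass(state), prop = prop,
    a0 = spec$hyper_shape, b0 = spec$hyper_rate, fe_sd = spec$fe_sd,
    iterations = as.integer(sweeps), burn_in = 0L, thin = 1L,
    use_temporal = spec$use_temporal && !data$collapse_years,
    do_gibbs = FALSE, adapt = FALSE, recenter = recenter)
  fs <- res$final_state
  out <- model_state(fs$mu, fs$alpha, fs$u, fs$v, fs$gamma,
                     fs$tau_u, fs$tau_v, fs$tau_g)
  attr(out, "acceptance") <- res$acceptance
  if (keep_draws) list(state = out, draws = res) else out
}

#' Fit the hierarchical model by MCMC
#'
#' Runs `spec$chains` independent chains from the master seed's per-chain
#' sub-streams, discards burn-in, thins, and computes split-R-hat for `mu`,
#' the precisions and three randomly chosen spatial effects.
#'
#' @param registry registry data frame.
#' @param graph an [area_graph()].
#' @param query stratum query, see [build_model_data()] and
#'   [validate_query()].
#' @param spec a [model_spec()].
#' @return a `bym_fit` object: per-chain draw matrices, acceptance rates,
#'   split-R-hat diagnostics, and the spec/query echo.
#' @export
fit_bym <- function(registry, graph, query, spec = model_spec()) {
  if (any(registry$person_years < 0)) ar_stop("negative person-years")
  if (all(registry$person_years == 0)) ar_stop("no population at risk")
  data <- build_model_data(registry, graph, query)
  I <- n_areas(graph)
  A <- length(data$age_groups)
  T <- length(data$years)
  crude <- (sum(data$y) + 0.5) / sum(data$n)
  init <- model_state(mu = log(crude), alpha = numeric(A), u = numeric(I),
                      v = numeric(I), gamma = numeric(T),
                      tau_u = 10, tau_v = 10, tau_g = 10)
  prop <- spec$proposal
  if (!spec$use_spatial) prop["u"] <- 0   # u pinned at its 0 init
  use_temporal <- spec$use_temporal && !data$collapse_years && T > 1L
  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(split_seed(spec$seed, paste0("chain", ch)))
    chains[[ch]] <- cpp_bym_chain(
      y = data$y, n = data$n,
      area = data$area - 1L, age = data$age - 1L, yr = data$year_idx - 1L,
      I = I, A = A, T = T,
      nbr0 = lapply(graph$nbr, function(x) as.integer(x - 1L)),
      edges0 = matrix(as.integer(graph$edges - 1L), ncol = 2L),
      comp0 = as.integer(graph$component - 1L), C = max(graph$component),
      init = unclass(init), prop = prop,
      a0 = spec$hyper_shape, b0 = spec$hyper_rate, fe_sd = spec$fe_sd,
      iterations = spec$iterations, burn_in = spec$burn_in, thin = spec$thin,
      use_temporal = use_temporal,
      do_gibbs = TRUE, adapt = spec$adapt, recenter = TRUE)
  }
  # three monitored spatial effects, chosen from a dedicated seed stream
  set.seed(split_seed(spec$seed, "rhat-pick"))
  mon_u <- sort(sample.int(I, min(3L, I)))
  rhat <- c(
    mu = split_rhat(lapply(chains, `[[`, "mu")),
    tau_u = split_rhat(lapply(chains, `[[`, "tau_u")),
    tau_v = split_rhat(lapply(chains, `[[`, "tau_v"))
  )
  if (use_temporal) {
    rhat <- c(rhat, tau_g = split_rhat(lapply(chains, `[[`, "tau_g")))
  }
  for (k in mon_u) {
    rhat[paste0("u[", k, "]")] <- split_rhat(lapply(chains, function(c) c$u[, k]))
  }
  acc <- do.call(rbind, lapply(chains, `[[`, "acceptance"))
  structure(list(
    chains = chains,
    data = data,
    spec = spec,
    use_temporal = use_temporal,
    area_ids = data$area_ids,
    area_names = graph$area_names,
    age_groups = data$age_groups,
    years = data$years,
    acceptance = acc,
    rhat = rhat,
    monitored_u = mon_u
  ), class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  M <- sum(vapply(x$chains, function(c) length(c$mu), integer(1)))
  cat(sprintf("bym_fit: %d chains, %d retained draws, %d areas, %d age groups, %d year(s)\n",
              length(x$chains), M, length(x$area_ids), length(x$age_groups),
              length(x$years)))
  cat("max split-Rhat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Stack retained draws across chains
#'
#' @param fit a `bym_fit`.
#' @return list of pooled draw matrices (`mu`, `alpha`, `u`, `v`, `gamma`,
#'   `tau_u`, `tau_v`, `tau_g`), rows = draws.
#' @export
stack_draws <- function(fit) {
  list(
    mu = unlist(lapply(fit$chains, `[[`, "mu")),
    alpha = do.call(rbind, lapply(fit$chains, `[[`, "alpha")),
    u = do.call(rbind, lapply(fit$chains, `[[`, "u")),
    v = do.call(rbind, lapply(fit$chains, `[[`, "v")),
    gamma = do.call(rbind, lapply(fit$chains, `[[`, "gamma")),
    tau_u = unlist(lapply(fit$chains, `[[`, "tau_u")),
    tau_v = unlist(lapply(fit$chains, `[[`, "tau_v")),
    tau_g = unlist(lapply(fit$chains, `[[`, "tau_g"))
  )
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Each chain is split in half; the potential scale reduction factor is
#' computed on the split halves.  Values near 1 indicate convergence.
#'
#' @param chains list of numeric vectors (one per chain).
#' @return scalar R-hat.
#' @export
split_rhat <- function(chains) {
  halves <- list()
  for (x in chains) {
    n2 <- floor(length(x) / 2)
    if (n2 < 2L) return(NA_real_)
    halves[[length(halves) + 1L]] <- x[seq_len(n2)]
    halves[[length(halves) + 1L]] <- x[(n2 + 1L):(2L * n2)]
  }
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## ---------------------------------------------------------------------------
## draw serialization

#' Write / read posterior draws as delimited text plus JSON metadata
#'
#' The draws file has one row per retained draw and scalar (`chain, draw,
#' param, index, value`); the sidecar `<path>.meta.json` echoes the spec,
#' query, label dictionaries, acceptance rates and R-hat values.
#'
#' @param fit a `bym_fit`.
#' @param path draws file path (the sidecar adds `.meta.json`).
#' @return `write_draws` returns `path` invisibly; `read_draws` a `bym_fit`
#'   (without the raw `data` component).
#' @export
write_draws <- function(fit, path) {
  pieces <- list()
  for (ch in seq_along(fit$chains)) {
    cc <- fit$chains[[ch]]
    M <- length(cc$mu)
    add <- function(param, values) {
      if (is.matrix(values)) {
        data.table::data.table(
          chain = ch, draw = rep(seq_len(M), ncol(values)), param = param,
          index = rep(seq_len(ncol(values)), each = M), value = as.vector(values))
      } else {
        data.table::data.table(chain = ch, draw = seq_len(M), param = param,
                               index = 1L, value = values)
      }
    }
    pieces[[length(pieces) + 1L]] <- data.table::rbindlist(list(
      add("mu", cc$mu), add("alpha", cc$alpha), add("u", cc$u), add("v", cc$v),
      add("gamma", cc$gamma), add("tau_u", cc$tau_u), add("tau_v", cc$tau_v),
      add("tau_g", cc$tau_g)))
  }
  data.table::fwrite(data.table::rbindlist(pieces), path)
  meta <- list(
    spec = fit$spec[setdiff(names(fit$spec), "proposal")],
    proposal = as.list(fit$spec$proposal),
    query = fit$data$query,
    area_ids = fit$area_ids,
    area_names = fit$area_names,
    age_groups = fit$age_groups,
    years = fit$years,
    use_temporal = fit$use_temporal,
    collapse_years = fit$data$collapse_years,
    acceptance = as.data.frame(fit$acceptance),
    rhat = as.list(fit$rhat),
    monitored_u = fit$monitored_u
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"), simplifyVector = TRUE)
  query <- as.list(meta$query)
  if (length(query$year_range) == 0L) query$year_range <- NULL
  chains <- list()
  for (ch in sort(unique(tab$chain))) {
    sub <- tab[tab$chain == ch, ]
    M <- max(sub$draw)
    grab <- function(param) {
      s <- sub[sub$param == param, ]
      k <- max(s$index)
      m <- matrix(NA_real_, M, k)
      m[cbind(s$draw, s$index)] <- s$value
      if (k == 1L) as.vector(m) else m
    }
    chains[[length(chains) + 1L]] <- list(
      mu = grab("mu"), alpha = as.matrix(grab("alpha")), u = as.matrix(grab("u")),
      v = as.matrix(grab("v")), gamma = as.matrix(grab("gamma")),
      tau_u = grab("tau_u"), tau_v = grab("tau_v"), tau_g = grab("tau_g"))
  }
  structure(list(
    chains = chains,
    data = list(query = query, collapse_years = meta$collapse_years),
    spec = meta$spec,
    use_temporal = meta$use_temporal,
    area_ids = meta$area_ids,
    area_names = meta$area_names,
    age_groups = meta$age_groups,
    years = meta$years,
    acceptance = meta$acceptance,
    rhat = unlist(meta$rhat),
    monitored_u = meta$monitored_u
  ), class = "bym_fit")
}
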