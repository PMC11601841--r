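# Synthetic registry generator: populations, ground-truth risk surfaces and
# Poisson event counts with known spatial/temporal structure, so the whole
# pipeline is testable without any real registry data.

#' Simulation settings for the synthetic registry
#'
#' Defaults describe a deliberately small but realistic registry world: a
#' 100-area lattice, four age groups with a colorectal-like incidence
#' gradient, five diagnosis years, two sexes and two race groups.  Baseline
#' age-specific rates are per person-year (2, 40, 120 and 200 per 100,000
#' across the four groups); the spatial marginal SD of 0.3 on the log-rate
#' scale gives roughly +/-35% area-level risk variation, typical of published
#' small-area cancer maps.
#'
#' @param rows,cols lattice dimensions used by [simulate_registry()].
#' @param age_groups age-group labels.
#' @param age_rates baseline age-specific rates per person-year.
#' @param age_shares population share per age group (must sum to 1).
#' @param years diagnosis years.
#' @param sexes,races stratum labels.
#' @param sex_offsets,race_offsets additive log-rate offsets per stratum.
#' @param site cancer-site label attached to generated rows.
#' @param spatial_sd marginal SD of the intrinsic CAR spatial effect
#'   (log-rate scale); 0 disables spatial structure.
#' @param temporal_sd innovation SD of the random-walk year effect; 0
#'   disables temporal structure.
#' @param late_stage_fraction binomial thinning probability producing
#'   late-stage counts from incident counts.
#' @param mortality_ratio multiplier on the incidence rate used for the
#'   mortality outcome.
#' @param pop_range range of per-area, per-year total person-years; totals
#'   are drawn log-uniformly.
#' @param pop_drift multiplicative per-year population drift (0 = constant).
#' @param overdispersion_sd SD of an optional lognormal rate multiplier
#'   (mean 1) used as a model-misspecification switch; 0 = none (default,
#'   matching the fitted model family).
#' @return a list of settings, class `sim_config`.
#' @export
sim_config <- function(rows = 10L, cols = 10L,
                       age_groups = c("0-39", "40-59", "60-74", "75+"),
                       age_rates = c(2e-5, 4e-4, 1.2e-3, 2e-3),
                       age_shares = c(0.5, 0.25, 0.15, 0.10),
                       years = 2015:2019,
                       sexes = c("female", "male"),
                       races = c("white", "black"),
                       sex_offsets = c(female = -0.15, male = 0.15),
                       race_offsets = c(white = 0, black = 0.12),
                       site = "colorectal",
                       spatial_sd = 0.3,
                       temporal_sd = 0.05,
                       late_stage_fraction = 0.5,
                       mortality_ratio = 0.4,
                       pop_range = c(500, 50000),
                       pop_drift = 0,
                       overdispersion_sd = 0) {
  stopifnot(length(age_rates) == length(age_groups),
            length(age_shares) == length(age_groups))
  cfg <- as.list(environment())
  names(cfg$age_rates) <- age_groups
  names(cfg$age_shares) <- age_groups
  structure(cfg, class = "sim_config")
}

#' Draw the ground-truth risk surface
#'
#' The spatial effect is drawn from the intrinsic CAR (ICAR) distribution on
#' the graph through the eigen-structure of the graph Laplacian, centered
#' within each connected component, and rescaled so the average theoretical
#' marginal SD equals `config$spatial_sd`.  The year effect is a centered
#' Gaussian random walk with innovation SD `config$temporal_sd`.  Singleton
#' components have spatial effect exactly 0 (centering forces it).
#'
#' @param graph an [area_graph()].
#' @param config a [sim_config()].
#' @param seed integer master seed; the truth uses the `"truth"` stream of
#'   [split_seed()].
#' @return a `truth_surface` list: `baseline_log_rate` (per age group),
#'   `spatial_effect` (per area), `temporal_effect` (per year),
#'   `stratum_offsets` (sex x race matrix), `seed`.
#' @export
simulate_truth <- function(graph, config = sim_config(), seed = 1L) {
  if (config$spatial_sd < 0 || config$temporal_sd < 0) {
    ar_stop("spatial_sd and temporal_sd must be non-negative")
  }
  set.seed(split_seed(seed, "truth"))
  n <- n_areas(graph)
  u <- numeric(n)
  if (config$spatial_sd > 0 && n > 1L) {
    marg_var <- numeric(n)
    for (cid in seq_len(max(graph$component))) {
      idx <- which(graph$component == cid)
      m <- length(idx)
      if (m < 2L) next  # singleton: stays 0
      W <- matrix(0, m, m)
      for (a in seq_len(m)) {
        nb <- intersect(graph$nbr[[idx[a]]], idx)
        W[a, match(nb, idx)] <- 1
      }
      Q <- diag(rowSums(W)) - W          # component Laplacian = ICAR precision
      eig <- eigen(Q, symmetric = TRUE)
      pos <- eig$values > max(eig$values) * 1e-10
      E <- eig$vectors[, pos, drop = FALSE]
      lam <- eig$values[pos]
      z <- as.vector(E %*% (rnorm(sum(pos)) / sqrt(lam)))
      u[idx] <- z - mean(z)              # exact centering per component
      marg_var[idx] <- rowSums(sweep(E^2, 2L, lam, `/`))
    }
    live <- marg_var > 0
    if (any(live)) u[live] <- u[live] * config$spatial_sd / sqrt(mean(marg_var[live]))
  }
  T <- length(config$years)
  gam <- numeric(T)
  if (config$temporal_sd > 0 && T > 1L) {
    walk <- cumsum(rnorm(T, 0, config$temporal_sd))
    gam <- walk - mean(walk)
  }
  off <- outer(config$sex_offsets[config$sexes], config$race_offsets[config$races], `+`)
  dimnames(off) <- list(config$sexes, config$races)
  structure(list(
    baseline_log_rate = log(config$age_rates),
    spatial_effect = stats::setNames(u, graph$area_ids),
    temporal_effect = stats::setNames(gam, config$years),
    stratum_offsets = off,
    seed = seed
  ), class = "truth_surface")
}

#' Synthesize person-years at risk per registry cell
#'
#' Per-area total person-years (per year) are drawn log-uniformly in
#' `config$pop_range`, split across age groups by `config$age_shares`, evenly
#' across sexes, and across races by a fixed 85/15 split; totals are constant
#' over years unless `config$pop_drift` is non-zero.
#'
#' @inheritParams simulate_truth
#' @return data frame with columns `area_id`, `age_group`, `year`, `sex`,
#'   `race`, `person_years`.
#' @export
synthetic_populations <- function(graph, config = sim_config(), seed = 1L) {
  if (abs(sum(config$age_shares) - 1) > 1e-9) {
    ar_stop("age_shares must sum to 1 (got ", sum(config$age_shares), ")")
  }
  set.seed(split_seed(seed, "populations"))
  n <- n_areas(graph)
  totals <- exp(runif(n, log(config$pop_range[1L]), log(config$pop_range[2L])))
  race_share <- stats::setNames(rep(1 / length(config$races), length(config$races)),
                                config$races)
  if (all(c("white", "black") %in% config$races)) {
    race_share[] <- 0; race_share["white"] <- 0.85; race_share["black"] <- 0.15
    other <- setdiff(config$races, c("white", "black"))
    if (length(other)) {
      race_share["white"] <- 0.85 - 0.05 * length(other)
      race_share[other] <- 0.05
    }
  }
  grid <- expand.grid(area_id = graph$area_ids, age_group = config$age_groups,
                      year = config$years, sex = config$sexes, race = config$races,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  yr0 <- min(config$years)
  grid$person_years <-
    totals[match(grid$area_id, graph$area_ids)] *
    config$age_shares[grid$age_group] *
    (1 / length(config$sexes)) *
    race_share[grid$race] *
    (1 + config$pop_drift)^(grid$year - yr0)
  rownames(grid) <- NULL
  grid
}

#' Simulate registry event counts from a truth surface
#'
#' Incident events are independent Poisson draws with mean
#' `person_years * exp(baseline + spatial + temporal + stratum offset)`;
#' late-stage counts are binomial thinnings of the incident counts with
#' probability `config$late_stage_fraction`; mortality counts are Poisson
#' draws at `config$mortality_ratio` times the incidence rate.  A lognormal
#' mean-one rate multiplier is applied when `config$overdispersion_sd > 0`.
#'
#' @param truth a `truth_surface` from [simulate_truth()].
#' @param populations person-years table from [synthetic_populations()].
#' @param config a [sim_config()].
#' @param seed integer master seed (stream `"counts"`).
#' @return a registry table: columns `area_id`, `age_group`, `year`, `sex`,
#'   `race`, `site`, `outcome`, `events`, `person_years`.
#' @export
simulate_counts <- function(truth, populations, config = sim_config(), seed = 1L) {
  if (any(populations$person_years < 0)) ar_stop("negative person-years")
  set.seed(split_seed(seed, "counts"))
  p <- populations
  lograte <- truth$baseline_log_rate[p$age_group] +
    truth$spatial_effect[p$area_id] +
    truth$temporal_effect[as.character(p$year)] +
    truth$stratum_offsets[cbind(p$sex, p$race)]
  rate <- exp(unname(lograte))
  if (config$overdispersion_sd > 0) {
    s <- config$overdispersion_sd
    rate <- rate * rlnorm(length(rate), -s^2 / 2, s)  # mean-one multiplier
  }
  inc <- rpois(nrow(p), p$person_years * rate)
  late <- rbinom(nrow(p), inc, config$late_stage_fraction)
  mort <- rpois(nrow(p), p$person_years * rate * config$mortality_ratio)
  out <- rbind(
    data.frame(p[c("area_id", "age_group", "year", "sex", "race")],
               site = config$site, outcome = "incidence", events = inc,
               person_years = p$person_years, stringsAsFactors = FALSE),
    data.frame(p[c("area_id", "age_group", "year", "sex", "race")],
               site = config$site, outcome = "late_stage", events = late,
               person_years = p$person_years, stringsAsFactors = FALSE),
    data.frame(p[c("area_id", "age_group", "year", "sex", "race")],
               site = config$site, outcome = "mortality", events = mort,
               person_years = p$person_years, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic registry fixture
#'
#' Convenience wrapper: lattice geography, populations, truth surface and
#' counts, all from one master seed via named streams.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @param graph optional pre-built [area_graph()]; defaults to the
#'   `config$rows` x `config$cols` queen lattice.
#' @return list with elements `graph`, `truth`, `populations`, `registry`.
#' @export
simulate_registry <- function(config = sim_config(), seed = 1L, graph = NULL) {
  if (is.null(graph)) graph <- make_lattice(config$rows, config$cols)
  truth <- simulate_truth(graph, config, seed)
  pops <- synthetic_populations(graph, config, seed)
  reg <- simulate_counts(truth, pops, config, seed)
  list(graph = graph, truth = truth, populations = pops, registry = reg)
}

#' Validate a registry table's structural invariants
#'
#' Checks column presence, non-negative counts and exposures, zero events on
#' zero exposure, key uniqueness, and that late-stage counts never exceed the
#' matching incident counts.
#'
#' @param registry a registry data frame.
#' @return the registry, invisibly; errors describe the first violation.
#' @export
validate_registry <- function(registry) {
  need <- c("area_id", "age_group", "year", "sex", "race", "site", "outcome",
            "events", "person_years")
  miss <- setdiff(need, names(registry))
  if (length(miss)) ar_stop("registry lacks column(s): ", paste(miss, collapse = ", "))
  if (any(registry$events < 0)) ar_stop("negative event counts")
  if (any(registry$person_years < 0)) ar_stop("negative person-years")
  if (any(registry$events > 0 & registry$person_years == 0)) {
    ar_stop("events recorded in cells with zero person-years")
  }
  key <- do.call(paste, c(registry[c("area_id", "age_group", "year", "sex",
                                     "race", "site", "outcome")], sep = "\r"))
  if (anyDuplicated(key)) ar_stop("duplicate registry keys")
  wide <- split(registry, registry$outcome)
  if (!is.null(wide$late_stage) && !is.null(wide$incidence)) {
    k <- function(d) do.call(paste, c(d[c("area_id", "age_group", "year", "sex",
                                          "race", "site")], sep = "\r"))
    m <- match(k(wide$late_stage), k(wide$incidence))
    bad <- !is.na(m) & wide$late_stage$events > wide$incidence$events[m]
    if (any(bad)) ar_stop("late_stage events exceed incidence events")
  }
  invisible(registry)
}

#' Read / write registry tables as delimited text
#'
#' Column order is fixed: `area_id, age_group, year, sex, race, site,
#' outcome, events, person_years`.
#'
#' @param registry a registry data frame.
#' @param path file path.
#' @return `write_registry` returns `path` invisibly; `read_registry` the
#'   validated data frame.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  cols <- c("area_id", "age_group", "year", "sex", "race", "site", "outcome",
            "events", "person_years")
  data.table::fwrite(registry[cols], path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  tab <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("area_id", "age_group", "sex", "race", "site", "outcome"))))
  validate_registry(tab)
}

#' Read / write a truth surface as a key-value sidecar
#'
#' @param truth a `truth_surface`.
#' @param path YAML file path.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(list(
    baseline_log_rate = as.list(truth$baseline_log_rate),
    spatial_effect = as.list(truth$spatial_effect),
    temporal_effect = as.list(truth$temporal_effect),
    stratum_offsets = list(values = as.vector(truth$stratum_offsets),
                           sexes = rownames(truth$stratum_offsets),
                           races = colnames(truth$stratum_offsets)),
    seed = truth$seed
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- yaml::read_yaml(path)
  off <- matrix(unlist(raw$stratum_offsets$values),
                nrow = length(raw$stratum_offsets$sexes),
                dimnames = list(raw$stratum_offsets$sexes, raw$stratum_offsets$races))
  structure(list(
    baseline_log_rate = unlist(raw$baseline_log_rate),
    spatial_effect = unlist(raw$spatial_effect),
    temporal_effect = unlist(raw$temporal_effect),
    stratum_offsets = off,
    seed = raw$seed
  ), class = "truth_surface")
}

#' Ground-truth age-adjusted rate per area
#'
#' Oracle utility for recovery tests: the exact (noise-free) direct
#' age-standardized rate per 100,000 implied by a truth surface for a given
#' stratum query, aggregating strata by their person-years mix.
#'
#' @param truth a `truth_surface`.
#' @param populations person-years table.
#' @param std a [std_population()].
#' @param year calendar year at which the temporal effect is taken; `NULL`
#'   averages the rate over years (person-years weighted).
#' @param sex,race stratum selection, `"all"` pools.
#' @return named numeric vector of true rates per area.
#' @export
true_adjusted_rates <- function(truth, populations, std, year = NULL,
                                sex = "all", race = "all") {
  p <- populations
  if (!identical(sex, "all")) p <- p[p$sex %in% sex, ]
  if (!identical(race, "all")) p <- p[p$race %in% race, ]
  if (!is.null(year)) p <- p[p$year %in% year, ]
  lr <- truth$baseline_log_rate[p$age_group] +
    truth$spatial_effect[p$area_id] +
    truth$temporal_effect[as.character(p$year)] +
    truth$stratum_offsets[cbind(p$sex, p$race)]
  p$expected <- p$person_years * exp(unname(lr))
  agg_e <- tapply(p$expected, list(p$area_id, p$age_group), sum)
  agg_n <- tapply(p$person_years, list(p$area_id, p$age_group), sum)
  rate_by_age <- agg_e / agg_n   # true age-specific rate per area
  w <- std$weights[colnames(rate_by_age)]
  out <- 1e5 * as.vector(rate_by_age %*% w)
  stats::setNames(out, rownames(rate_by_age))[truth$spatial_effect |> names()]
}
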