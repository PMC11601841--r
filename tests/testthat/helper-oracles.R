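# Shared fixtures (cached across test files) and independent brute-force
# oracles.  Oracles are written as plain term-by-term loops, deliberately not
# reusing any package internals they are meant to check.

.fixture_cache <- new.env(parent = emptyenv())

fixture_world <- function(seed = 1L) {
  key <- paste0("world", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_registry(sim_config(), seed = seed)
  }
  .fixture_cache[[key]]
}

fixture_fit <- function(seed = 1L) {
  key <- paste0("fit", seed)
  if (is.null(.fixture_cache[[key]])) {
    w <- fixture_world(seed)
    q <- validate_query("colorectal", outcome = "incidence")
    .fixture_cache[[key]] <- fit_bym(w$registry, w$graph, q,
                                     model_spec(seed = seed))
  }
  .fixture_cache[[key]]
}

fixture_rows <- function(seed = 1L) {
  key <- paste0("rows", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- area_estimates(fixture_fit(seed),
                                            fixture_world(seed)$registry,
                                            std_flat())
  }
  .fixture_cache[[key]]
}

# term-by-term log posterior, straight from the model definition
brute_log_posterior <- function(state, data, graph, spec) {
  lp <- 0
  for (k in seq_along(data$y)) {
    lam <- data$n[k] * exp(state$mu + state$alpha[data$age[k]] +
                             state$u[data$area[k]] + state$v[data$area[k]] +
                             state$gamma[data$year_idx[k]])
    lp <- lp + data$y[k] * log(lam) - lam - lgamma(data$y[k] + 1)
  }
  I <- length(graph$area_ids)
  C <- max(graph$component)
  lp <- lp + 0.5 * (I - C) * log(state$tau_u)
  for (i in seq_len(I)) {
    for (j in graph$nbr[[i]]) {
      if (j > i) lp <- lp - 0.5 * state$tau_u * (state$u[i] - state$u[j])^2
    }
  }
  for (i in seq_len(I)) {
    lp <- lp - 0.5 * log(2 * pi) + 0.5 * log(state$tau_v) -
      0.5 * state$tau_v * state$v[i]^2
  }
  T <- length(data$years)
  temporal <- spec$use_temporal && T > 1 && !data$collapse_years
  if (temporal) {
    lp <- lp + 0.5 * (T - 1) * log(state$tau_g)
    for (t in 2:T) {
      lp <- lp - 0.5 * state$tau_g * (state$gamma[t] - state$gamma[t - 1])^2
    }
  }
  for (x in c(state$mu, state$alpha)) {
    lp <- lp - 0.5 * log(2 * pi) - log(spec$fe_sd) - x^2 / (2 * spec$fe_sd^2)
  }
  a <- spec$hyper_shape; b <- spec$hyper_rate
  gpr <- function(tau) a * log(b) - lgamma(a) + (a - 1) * log(tau) - b * tau
  lp <- lp + gpr(state$tau_u) + gpr(state$tau_v)
  if (temporal) lp <- lp + gpr(state$tau_g)
  lp
}

# brute-force Moran's I against a binary symmetric adjacency
moran_i <- function(x, graph) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) {
    for (j in graph$nbr[[i]]) {
      num <- num + xc[i] * xc[j]
      s0 <- s0 + 1
    }
  }
  (n / s0) * num / sum(xc^2)
}

# brute-force grid edge count for a rows x cols lattice
brute_lattice_edges <- function(rows, cols, rule) {
  cnt <- 0L
  for (r1 in seq_len(rows)) for (c1 in seq_len(cols)) {
    for (r2 in seq_len(rows)) for (c2 in seq_len(cols)) {
      if (r2 < r1 || (r2 == r1 && c2 <= c1)) next
      dr <- abs(r1 - r2); dc <- abs(c1 - c2)
      adj <- if (rule == "rook") dr + dc == 1L else max(dr, dc) == 1L
      if (adj) cnt <- cnt + 1L
    }
  }
  cnt
}

# minimal hand-built fit object for draw-level estimate tests
fake_fit <- function(mu, alpha, u, v, gamma = NULL, area_ids = NULL,
                     age_groups = NULL, years = 0L, use_temporal = FALSE) {
  alpha <- as.matrix(alpha); u <- as.matrix(u); v <- as.matrix(v)
  if (is.null(gamma)) gamma <- matrix(0, length(mu), length(years))
  if (is.null(area_ids)) area_ids <- paste0("A", seq_len(ncol(u)))
  if (is.null(age_groups)) age_groups <- paste0("g", seq_len(ncol(alpha)))
  structure(list(
    chains = list(list(mu = mu, alpha = alpha, u = u, v = v,
                       gamma = as.matrix(gamma),
                       tau_u = rep(1, length(mu)), tau_v = rep(1, length(mu)),
                       tau_g = rep(1, length(mu)))),
    data = list(query = list(site = "colorectal", outcome = "incidence",
                             sex = "all", race = "all", year_range = NULL,
                             site_label = "colorectal"),
                collapse_years = FALSE),
    area_ids = area_ids, area_names = area_ids,
    age_groups = age_groups, years = years,
    use_temporal = use_temporal
  ), class = "bym_fit")
}

# random small model instance shared by density-oracle tests
make_tiny_instance <- function(seed) {
  set.seed(seed)
  graph <- adjacency_from_edgelist(rbind(c("A", "B"), c("B", "C")),
                                   c("A", "B", "C"))
  cells <- expand.grid(area_id = c("A", "B", "C"), age_group = c("a1", "a2"),
                       year = 2015:2016, sex = "persons", race = "allrace",
                       stringsAsFactors = FALSE)
  cells$site <- "colorectal"; cells$outcome <- "incidence"
  cells$person_years <- runif(nrow(cells), 100, 1000)
  cells$events <- rpois(nrow(cells), cells$person_years * 0.01)
  data <- build_model_data(cells, graph,
                           list(site = "colorectal", outcome = "incidence",
                                sex = "all", race = "all"))
  center <- function(x) x - mean(x)
  state <- model_state(
    mu = rnorm(1, log(0.01), 0.3),
    alpha = center(rnorm(2, 0, 0.3)),
    u = center(rnorm(3, 0, 0.3)),
    v = rnorm(3, 0, 0.3),
    gamma = center(rnorm(2, 0, 0.1)),
    tau_u = runif(1, 0.5, 2), tau_v = runif(1, 0.5, 2),
    tau_g = runif(1, 0.5, 2))
  list(graph = graph, data = data, state = state)
}
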