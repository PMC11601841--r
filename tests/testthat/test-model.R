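# The hierarchical model: density oracle, conjugate updates, sweep
# stationarity, constraint conservation, convergence and recovery basics.

test_that("log_posterior matches a closed-form hand sum on a single cell", {
  graph <- make_lattice(1, 1)
  reg <- data.frame(area_id = "Z00001", age_group = "all", year = 2015,
                    sex = "persons", race = "allrace", site = "colorectal",
                    outcome = "incidence", events = 0L, person_years = 1)
  data <- build_model_data(reg, graph,
                           list(site = "colorectal", outcome = "incidence",
                                sex = "all", race = "all"))
  spec <- model_spec()
  state <- model_state(mu = 0, alpha = 0, u = 0, v = 0, gamma = 0,
                       tau_u = 1, tau_v = 1, tau_g = 1)
  # Poisson: y=0, n=1, mu=0 -> -exp(0) = -1; remaining terms in closed form
  expected <- -1 +
    (-0.5 * log(2 * pi)) +                                  # v_1 ~ N(0, 1)
    2 * (-0.5 * log(2 * pi) - log(10)) +                    # mu, alpha_1 priors
    2 * (log(0.01) - 0.01)                                  # Gamma(1, .01) at tau=1
  expect_equal(log_posterior(state, data, graph, spec), expected, tolerance = 1e-12)
})

test_that("log_posterior rejects states violating the sum-to-zero constraints", {
  inst <- make_tiny_instance(1)
  spec <- model_spec()
  bad <- inst$state
  bad$u <- bad$u + 0.5   # constant shift breaks per-component centering
  expect_error(log_posterior(bad, inst$data, inst$graph, spec), "sum-to-zero")
  bad2 <- inst$state
  bad2$tau_v <- -1
  expect_error(log_posterior(bad2, inst$data, inst$graph, spec), "positive")
})

test_that("log_posterior equals brute-force term-by-term summation on random instances", {
  spec <- model_spec()
  for (s in 1:20) {
    inst <- make_tiny_instance(s)
    expect_equal(log_posterior(inst$state, inst$data, inst$graph, spec),
                 brute_log_posterior(inst$state, inst$data, inst$graph, spec),
                 tolerance = 1e-10, info = paste("instance", s))
  }
})

test_that("precision full conditionals have the hand-computed Gamma parameters", {
  graph <- adjacency_from_edgelist(rbind(c("A", "B"), c("B", "C")),
                                   c("A", "B", "C"))
  reg <- data.frame(area_id = c("A", "B", "C"), age_group = "all", year = 2015,
                    sex = "persons", race = "allrace", site = "colorectal",
                    outcome = "incidence", events = 1L, person_years = 100)
  data <- build_model_data(reg, graph,
                           list(site = "colorectal", outcome = "incidence",
                                sex = "all", race = "all"))
  spec <- model_spec()  # Gamma(1, 0.01) hyperprior

  st0 <- model_state(mu = 0, alpha = 0, u = c(0, 0, 0), v = c(0, 0, 0),
                     gamma = 0, tau_u = 1, tau_v = 1, tau_g = 1)
  pp0 <- precision_posteriors(st0, data, graph, spec)
  expect_equal(unname(pp0$tau_u), c(1 + (3 - 1) / 2, 0.01))  # qf = 0

  st1 <- st0; st1$u <- c(-1, 0, 1)  # path edges: (-1-0)^2 + (0-1)^2 = 2
  pp1 <- precision_posteriors(st1, data, graph, spec)
  expect_equal(unname(pp1$tau_u), c(2, 0.01 + 1))
})

test_that("Gibbs precision draws have the Gamma full-conditional mean", {
  graph <- make_lattice(2, 5)
  reg <- data.frame(area_id = graph$area_ids, age_group = "all", year = 2015,
                    sex = "persons", race = "allrace", site = "colorectal",
                    outcome = "incidence", events = 1L, person_years = 100)
  data <- build_model_data(reg, graph,
                           list(site = "colorectal", outcome = "incidence",
                                sex = "all", race = "all"))
  spec <- model_spec()
  set.seed(99)
  v <- rnorm(10, 0, 0.5)
  st <- model_state(mu = 0, alpha = 0, u = numeric(10), v = v, gamma = 0,
                    tau_u = 1, tau_v = 1, tau_g = 1)
  set.seed(100)
  draws <- replicate(10000, gibbs_update_precisions(st, data, graph, spec)$tau_v)
  m_exp <- (1 + 10 / 2) / (0.01 + sum(v^2) / 2)   # Gamma moment oracle
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m_exp), 3 * se)
})

test_that("zero-SD proposals leave the state exactly unchanged", {
  inst <- make_tiny_instance(3)
  frozen <- c(mu = 0, alpha = 0, u = 0, v = 0, gamma = 0, u_scale = 0)
  set.seed(1)
  out <- metropolis_sweep(inst$state, inst$data, inst$graph, model_spec(),
                          sweeps = 5, prop_sd = frozen, recenter = FALSE)
  for (f in c("mu", "alpha", "u", "v", "gamma")) {
    expect_equal(out[[f]], inst$state[[f]], tolerance = 0)
  }
  # with recentering of an already-centered state, changes are at float noise
  set.seed(1)
  out2 <- metropolis_sweep(inst$state, inst$data, inst$graph, model_spec(),
                           sweeps = 5, prop_sd = frozen)
  expect_equal(out2$u, inst$state$u, tolerance = 1e-12)
  expect_equal(out2$mu, inst$state$mu, tolerance = 1e-12)
})

test_that("a single free coordinate reaches its grid-normalized full conditional", {
  # Single area, one age, one year: only v_1 moves; every other block frozen.
  graph <- make_lattice(1, 1)
  reg <- data.frame(area_id = "Z00001", age_group = "all", year = 2015,
                    sex = "persons", race = "allrace", site = "colorectal",
                    outcome = "incidence", events = 3L, person_years = 100)
  data <- build_model_data(reg, graph,
                           list(site = "colorectal", outcome = "incidence",
                                sex = "all", race = "all"))
  spec <- model_spec()
  mu0 <- log(0.03); tau_v <- 4
  st <- model_state(mu = mu0, alpha = 0, u = 0, v = 0, gamma = 0,
                    tau_u = 1, tau_v = tau_v, tau_g = 1)
  set.seed(7)
  res <- metropolis_sweep(st, data, graph, spec, sweeps = 50000,
                          prop_sd = c(mu = 0, alpha = 0, u = 0, v = 0.6,
                                      gamma = 0, u_scale = 0),
                          recenter = FALSE, keep_draws = TRUE)
  v <- as.vector(res$draws$v)

  # oracle: normalize the exact full conditional on a fine grid
  grid <- seq(-3, 3, length.out = 4001)
  logf <- 3 * grid - 100 * exp(mu0 + grid) - tau_v * grid^2 / 2
  f <- exp(logf - max(logf)); f <- f / sum(f)
  breaks <- quantile(grid, seq(0, 1, length.out = 13))
  p_exp <- tapply(f, cut(grid, breaks, include.lowest = TRUE), sum)
  p_obs <- table(cut(v, breaks, include.lowest = TRUE)) / length(v)

  # 3 Monte-Carlo SEs with autocorrelation-adjusted effective sample size
  rho <- acf(v, lag.max = 200, plot = FALSE)$acf[-1]
  n_eff <- length(v) / (1 + 2 * sum(pmax(rho, 0)))
  for (b in seq_along(p_exp)) {
    tol <- 3 * sqrt(p_exp[b] * (1 - p_exp[b]) / n_eff) + 2 / length(v)
    expect_lt(abs(p_obs[b] - p_exp[b]), tol)
  }
})

test_that("identical seeds give bit-identical trajectories", {
  w <- fixture_world()
  q <- validate_query("colorectal", outcome = "incidence")
  spec <- model_spec(iterations = 600, burn_in = 100, thin = 5, chains = 1,
                     seed = 31)
  f1 <- fit_bym(w$registry, w$graph, q, spec)
  f2 <- fit_bym(w$registry, w$graph, q, spec)
  expect_identical(f1$chains[[1]]$u, f2$chains[[1]]$u)
  expect_identical(f1$chains[[1]]$tau_u, f2$chains[[1]]$tau_u)
})

test_that("sum-to-zero constraints are conserved in every retained draw", {
  fit <- fixture_fit()
  for (ch in fit$chains) {
    expect_lt(max(abs(rowSums(ch$alpha))), 1e-10)
    expect_lt(max(abs(rowSums(ch$gamma))), 1e-10)
    expect_lt(max(abs(rowSums(ch$u))), 1e-10)   # fixture graph is connected
  }
})

test_that("log_posterior is invariant under consistent area permutation", {
  spec <- model_spec()
  inst <- make_tiny_instance(12)
  perm <- c(3L, 1L, 2L)
  ids <- inst$graph$area_ids[perm]
  gperm <- adjacency_from_edgelist(
    cbind(inst$graph$area_ids[inst$graph$edges[, 1]],
          inst$graph$area_ids[inst$graph$edges[, 2]]), ids)
  dperm <- inst$data
  dperm$area <- match(inst$graph$area_ids[inst$data$area], ids)
  sperm <- inst$state
  sperm$u <- inst$state$u[match(ids, inst$graph$area_ids)]
  sperm$v <- inst$state$v[match(ids, inst$graph$area_ids)]
  expect_equal(log_posterior(sperm, dperm, gperm, spec),
               log_posterior(inst$state, inst$data, inst$graph, spec),
               tolerance = 1e-12)
})

test_that("single-area fit matches the conjugate Gamma oracle", {
  graph <- make_lattice(1, 1)
  reg <- data.frame(area_id = "Z00001", age_group = "all", year = 2015,
                    sex = "persons", race = "allrace", site = "colorectal",
                    outcome = "incidence", events = 5L, person_years = 1000)
  q <- validate_query("colorectal", outcome = "incidence")
  fit <- fit_bym(reg, graph, q, model_spec(seed = 2))
  dr <- stack_draws(fit)
  rate <- exp(dr$mu + dr$u[, 1] + dr$v[, 1])
  # flat-ish priors: posterior of the rate is close to Gamma(5, 1000)
  band <- qgamma(c(0.025, 0.975), shape = 5, rate = 1000)
  expect_gt(mean(rate), band[1])
  expect_lt(mean(rate), band[2])
})

test_that("spatial variance estimate orders correctly across truth settings", {
  q <- validate_query("colorectal", outcome = "incidence")
  spec <- model_spec(iterations = 3000, burn_in = 500, thin = 5, chains = 1,
                     seed = 4)
  sd_hat <- vapply(c(0, 0.3), function(ssd) {
    w <- simulate_registry(sim_config(rows = 6, cols = 6, spatial_sd = ssd),
                           seed = 21)
    fit <- fit_bym(w$registry, w$graph, q, spec)
    mean(1 / sqrt(stack_draws(fit)$tau_u))
  }, numeric(1))
  expect_lt(sd_hat[1], sd_hat[2])
})

test_that("fit rejects impossible inputs", {
  w <- fixture_world()
  q <- validate_query("colorectal", outcome = "incidence")
  bad <- w$registry
  bad$person_years <- 0
  expect_error(fit_bym(bad, w$graph, q, model_spec()), "no population at risk")
  bad2 <- w$registry
  bad2$person_years[1] <- -5
  expect_error(fit_bym(bad2, w$graph, q, model_spec()), "negative")
})

test_that("year-range queries collapse years and drop the temporal term", {
  w <- fixture_world()
  q <- validate_query("colorectal", outcome = "incidence",
                      year_range = c(2015, 2019))
  data <- build_model_data(w$registry, w$graph, q)
  expect_identical(length(data$years), 1L)
  expect_true(data$collapse_years)
  # pooled person-years equal the sum over the five years
  tot <- sum(w$registry$person_years[w$registry$outcome == "incidence"])
  expect_equal(sum(data$n), tot, tolerance = 1e-9)
})

test_that("posterior draws serialize and reload losslessly", {
  fit <- fixture_fit()
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read_draws(path)
  expect_equal(back$chains[[1]]$u, fit$chains[[1]]$u, tolerance = 1e-12)
  expect_equal(back$chains[[2]]$tau_u, fit$chains[[2]]$tau_u, tolerance = 1e-12)
  expect_identical(back$area_ids, fit$area_ids)
  expect_equal(unname(back$rhat), unname(fit$rhat), tolerance = 1e-9)
})
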