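# Posterior draws -> published measures: direct age-standardized rates per
# 100,000 person-years, exceedance ("risk") probabilities against the
# population-weighted state reference, hotspot flags, uncertainty classes and
# suppression-aware raw-rate comparisons.

#' Per-draw, per-area age-adjusted rates
#'
#' For draw `m` and area `i`:
#' `R_i^(m) = 100000 * sum_a w_a * exp(mu + alpha_a + u_i + v_i + gamma_t)`,
#' with the year effect taken at the queried year, or omitted entirely for a
#' collapsed year-range fit.
#'
#' @param fit a `bym_fit`.
#' @param std a [std_population()] over the fit's age groups.
#' @param year calendar year at which the temporal effect is evaluated;
#'   defaults to the latest modeled year.  Ignored for year-range fits.
#' @param scale rate denominator, 100,000 by convention.
#' @return draws x areas matrix of rates (columns named by area id).
#' @export
age_adjusted_rate_draws <- function(fit, std, year = NULL, scale = 1e5) {
  if (!setequal(names(std$weights), fit$age_groups)) {
    ar_stop("standard-population age groups do not match the model: ",
            paste(fit$age_groups, collapse = ", "))
  }
  w <- std$weights[fit$age_groups]
  dr <- stack_draws(fit)
  gamma_t <- if (fit$use_temporal) {
    if (is.null(year)) year <- max(fit$years)
    t_idx <- match(year, fit$years)
    if (is.na(t_idx)) ar_stop("year ", year, " not among modeled years")
    dr$gamma[, t_idx]
  } else {
    0
  }
  # draws x ages matrix of exp(mu + alpha_a + gamma_t), then area factors
  base <- exp(dr$mu + gamma_t + dr$alpha)       # recycles mu+gamma over columns
  agewt <- as.vector(base %*% w)                # per-draw age-standardized base
  out <- scale * agewt * exp(dr$u + dr$v)
  colnames(out) <- fit$area_ids
  out
}

#' Per-draw state-reference age-adjusted rate
#'
#' The state age-specific rate is the person-years-weighted mean of the area
#' age-specific rates, standardized with the same weights and scale, so the
#' reference equals the observable state rate in expectation.
#'
#' @inheritParams age_adjusted_rate_draws
#' @param populations person-years per area and age group for the queried
#'   stratum: either a data frame with `area_id`, `age_group`, `person_years`
#'   (summed if years/strata repeat) or an areas x ages matrix.
#' @return numeric vector, one state rate per draw.
#' @export
state_reference_draws <- function(fit, populations, std, year = NULL,
                                  scale = 1e5) {
  w <- std$weights[fit$age_groups]
  P <- population_matrix(populations, fit$area_ids, fit$age_groups)
  if (sum(P) <= 0) ar_stop("zero total person-years")
  dr <- stack_draws(fit)
  gamma_t <- if (fit$use_temporal) {
    if (is.null(year)) year <- max(fit$years)
    dr$gamma[, match(year, fit$years)]
  } else {
    0
  }
  base <- exp(dr$mu + gamma_t + dr$alpha)       # draws x ages
  expuv <- exp(dr$u + dr$v)                     # draws x areas
  # pooled age-specific rate_a^(m) = sum_i P_ia r_ia / sum_i P_ia
  num <- expuv %*% P                            # draws x ages, times base_a below
  pooled <- sweep(num, 2L, colSums(P), `/`) * base
  scale * as.vector(pooled %*% w)
}

#' @keywords internal
population_matrix <- function(populations, area_ids, age_groups) {
  if (is.matrix(populations)) {
    P <- populations[area_ids, age_groups, drop = FALSE]
  } else {
    need <- c("area_id", "age_group", "person_years")
    stopifnot(all(need %in% names(populations)))
    agg <- tapply(populations$person_years,
                  list(factor(populations$area_id, area_ids),
                       factor(populations$age_group, age_groups)), sum)
    P <- as.matrix(agg)
    P[is.na(P)] <- 0
  }
  if (anyNA(P)) ar_stop("populations do not cover all areas/age groups")
  P
}

#' Exceedance (risk) probability per area
#'
#' Fraction of retained draws in which an area's age-adjusted rate exceeds
#' the state reference; a value of 0.95 means a high probability that the
#' area's cancer burden is greater than the overall state.  Ties count as
#' not exceeding (conservative).
#'
#' @param area_rate_draws draws x areas matrix.
#' @param state_rate_draws numeric vector of the same draw count.
#' @return numeric vector in `[0, 1]`, one per area.
#' @export
risk_probability <- function(area_rate_draws, state_rate_draws) {
  if (nrow(area_rate_draws) == 0L) ar_stop("zero posterior draws")
  if (nrow(area_rate_draws) != length(state_rate_draws)) {
    ar_stop("draw counts differ between area and state rates")
  }
  colMeans(area_rate_draws > state_rate_draws)
}

#' Hotspot flags: the top fraction of area rates
#'
#' Flags the `ceiling(fraction * N)` highest rates; ties at the threshold are
#' all flagged, so the flagged count can only exceed the nominal count
#' through ties.
#'
#' @param rates point estimate per area.
#' @param fraction top fraction to flag, default 0.10 (the "top 10%" rule).
#' @return logical vector per area.
#' @export
#' @examples
#' sum(hotspot_flags(1:100 / 100))  # 10
hotspot_flags <- function(rates, fraction = 0.10) {
  stopifnot(length(rates) >= 1L, fraction > 0, fraction < 1)
  k <- ceiling(fraction * length(rates))
  threshold <- sort(rates, decreasing = TRUE)[k]
  rates >= threshold
}

#' Classify posterior SDs into low / medium / high uncertainty
#'
#' Tertile split at the 1/3 and 2/3 empirical quantiles of the SDs
#' (type-7 quantiles): `sd <= q(1/3)` is low, `<= q(2/3)` medium, else high.
#' With fewer than three areas every SD is labelled low, with a warning.
#'
#' @param rate_sds non-negative posterior SDs per area.
#' @return character vector of labels in `c("low", "medium", "high")`.
#' @export
uncertainty_classes <- function(rate_sds) {
  if (any(rate_sds < 0)) ar_stop("negative rate SD")
  if (length(rate_sds) < 3L) {
    ar_warn("fewer than 3 areas: all uncertainty classes set to \"low\"")
    return(rep("low", length(rate_sds)))
  }
  q <- quantile(rate_sds, c(1, 2) / 3, type = 7, names = FALSE)
  ifelse(rate_sds <= q[1L], "low", ifelse(rate_sds <= q[2L], "medium", "high"))
}

#' Direct (raw) age-standardized rate with small-count suppression
#'
#' The unsmoothed comparator: when the total event count reaches the
#' suppression threshold, the direct standardized rate is reported; otherwise
#' it is suppressed — the modeled estimate remains available alongside, which
#' is the point of the tool.
#'
#' @param events_total total observed events for the area.
#' @param person_years_total total person-years (kept for the exported
#'   record; the age-specific rates already encode the exposure).
#' @param age_rates observed age-specific rates (events/person-years per age
#'   group, 0 where there is no exposure), named by age group.
#' @param std a [std_population()].
#' @param threshold minimum events for release, default 16 (common registry
#'   convention); the boundary count itself is reported.
#' @param scale rate denominator.
#' @return list with `rate` (NA when suppressed) and `suppressed` flag.
#' @export
raw_rate_with_suppression <- function(events_total, person_years_total,
                                      age_rates, std, threshold = 16L,
                                      scale = 1e5) {
  stopifnot(threshold >= 0)
  if (events_total < threshold) {
    return(list(rate = NA_real_, suppressed = TRUE))
  }
  w <- std$weights[names(age_rates)]
  if (anyNA(w)) ar_stop("age groups of rates and standard population differ")
  list(rate = scale * sum(w * age_rates), suppressed = FALSE)
}

#' Validate and normalize a site/stratum query
#'
#' Sex-restricted sites (prostate is male; breast and cervical are female)
#' reject an incompatible explicit sex in `"strict"` mode or coerce it in
#' `"coerce"` mode; a pooled `"all"` sex is always narrowed to the site's sex
#' so no null stratum can be requested.
#'
#' @param site one of the configured site keys (see [site_config()]).
#' @param sex `"all"` or a sex label.
#' @param race `"all"` or a race label.
#' @param outcome `"incidence"`, `"late_stage"` or `"mortality"`.
#' @param year_range optional length-2 year range that pools years.
#' @param mode `"strict"` (reject incompatible sex) or `"coerce"`.
#' @param sites site configuration, defaults to [site_config()].
#' @return normalized query list (`site`, `sex`, `race`, `outcome`,
#'   `year_range`, `site_label`).
#' @export
#' @examples
#' validate_query("prostate", sex = "all")$sex  # "male"
validate_query <- function(site, sex = "all", race = "all",
                           outcome = c("incidence", "late_stage", "mortality"),
                           year_range = NULL, mode = c("strict", "coerce"),
                           sites = site_config()) {
  outcome <- match.arg(outcome)
  mode <- match.arg(mode)
  if (!site %in% names(sites)) {
    ar_stop("unknown site \"", site, "\"; configured sites: ",
            paste(names(sites), collapse = ", "))
  }
  restricted <- sites[[site]]$sex
  if (!is.na(restricted)) {
    if (identical(sex, "all")) {
      sex <- restricted
    } else if (!identical(sex, restricted)) {
      if (mode == "strict") {
        ar_stop(sites[[site]]$label, " is restricted to the ", restricted,
                " sex group; the \"", sex, "\" stratum would display null data")
      }
      sex <- restricted
    }
  }
  if (!is.null(year_range)) {
    stopifnot(length(year_range) == 2L)
    year_range <- sort(as.integer(year_range))
  }
  list(site = site, sex = sex, race = race, outcome = outcome,
       year_range = year_range, site_label = sites[[site]]$label)
}

#' Assemble the exportable area-estimate table
#'
#' One row per area: posterior-mean age-adjusted rate, its SD and equal-
#' tailed 95% interval, the exceedance probability against the state
#' reference, the hotspot flag, the uncertainty class, the (possibly
#' suppressed) raw rate, and observed totals.
#'
#' @param fit a `bym_fit`.
#' @param registry the registry data frame the fit was built from.
#' @param std a [std_population()].
#' @param year year at which rates are evaluated (default: latest modeled
#'   year); ignored for year-range fits.
#' @param hotspot_fraction top fraction flagged as hotspots.
#' @param suppression_threshold minimum events for releasing a raw rate.
#' @return data frame of class `area_estimates`.
#' @export
area_estimates <- function(fit, registry, std, year = NULL,
                           hotspot_fraction = 0.10,
                           suppression_threshold = 16L) {
  query <- fit$data$query
  d <- registry[registry$site == query$site & registry$outcome == query$outcome, ]
  if (!identical(query$sex %||% "all", "all")) d <- d[d$sex == query$sex, ]
  if (!identical(query$race %||% "all", "all")) d <- d[d$race == query$race, ]
  if (!is.null(query$year_range)) {
    d <- d[d$year >= query$year_range[1L] & d$year <= query$year_range[2L], ]
  }
  if (fit$use_temporal && is.null(year)) year <- max(fit$years)

  rate_draws <- age_adjusted_rate_draws(fit, std, year = year)
  state_draws <- state_reference_draws(fit, d, std, year = year)
  rp <- risk_probability(rate_draws, state_draws)
  rate <- colMeans(rate_draws)
  rate_sd <- apply(rate_draws, 2L, sd)
  ci <- apply(rate_draws, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)

  ids <- fit$area_ids
  ev <- tapply(d$events, factor(d$area_id, ids), sum, default = 0L)
  py <- tapply(d$person_years, factor(d$area_id, ids), sum, default = 0)
  ev_age <- tapply(d$events, list(factor(d$area_id, ids),
                                  factor(d$age_group, fit$age_groups)),
                   sum, default = 0L)
  py_age <- tapply(d$person_years, list(factor(d$area_id, ids),
                                        factor(d$age_group, fit$age_groups)),
                   sum, default = 0)
  raw <- numeric(length(ids)); supp <- logical(length(ids))
  for (i in seq_along(ids)) {
    ar <- ifelse(py_age[i, ] > 0, ev_age[i, ] / py_age[i, ], 0)
    names(ar) <- fit$age_groups
    rr <- raw_rate_with_suppression(ev[i], py[i], ar, std,
                                    threshold = suppression_threshold)
    raw[i] <- if (rr$suppressed) NA_real_ else rr$rate
    supp[i] <- rr$suppressed
  }
  out <- data.frame(
    area_id = ids,
    area_name = fit$area_names %||% ids,
    rate = unname(rate),
    rate_sd = unname(rate_sd),
    ci_low = ci[1L, ],
    ci_high = ci[2L, ],
    risk_prob = unname(rp),
    hotspot = unname(hotspot_flags(rate, hotspot_fraction)),
    uncertainty = unname(uncertainty_classes(rate_sd)),
    raw_rate = raw,
    suppressed = supp,
    events_total = as.integer(ev),
    person_years_total = as.numeric(py),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "query") <- query
  attr(out, "year") <- if (fit$use_temporal) year else NULL
  attr(out, "year_label") <- if (fit$use_temporal) {
    as.character(year)
  } else if (!is.null(query$year_range)) {
    paste(query$year_range, collapse = "-")
  } else {
    "all"
  }
  class(out) <- c("area_estimates", "data.frame")
  out
}

#' Filter an estimates table with a small query grammar
#'
#' The query is a conjunction of clauses joined by `&` (or `;`):
#' \itemize{
#'   \item `id=PREFIX` — area-id prefix match;
#'   \item `name=TEXT` — case-insensitive substring match on the area name;
#'   \item `FIELD OP VALUE` — numeric comparison with `OP` one of
#'     `<, <=, >, >=, ==` over `rate`, `risk_prob`, `rate_sd`,
#'     `person_years_total`.
#' }
#' An empty query returns the rows unchanged.
#'
#' @param rows an [area_estimates()] data frame.
#' @param query filter string, e.g. `"id=Z000 & risk_prob>=0.95"`.
#' @return the matching subset of `rows`.
#' @export
filter_estimates <- function(rows, query) {
  if (is.null(query) || !nzchar(trimws(query))) return(rows)
  keep <- rep(TRUE, nrow(rows))
  for (clause in trimws(strsplit(query, "[;&]")[[1L]])) {
    if (!nzchar(clause)) next
    if (grepl("^id=", clause)) {
      keep <- keep & startsWith(rows$area_id, sub("^id=", "", clause))
    } else if (grepl("^name=", clause)) {
      pat <- tolower(sub("^name=", "", clause))
      keep <- keep & grepl(pat, tolower(rows$area_name), fixed = TRUE)
    } else {
      m <- regmatches(clause,
                      regexec("^(rate|risk_prob|rate_sd|person_years_total)\\s*(<=|>=|==|<|>)\\s*(-?[0-9.eE+]+)$",
                              clause))[[1L]]
      if (length(m) == 0L) {
        ar_stop("malformed or unknown filter clause: \"", clause, "\"")
      }
      vals <- rows[[m[2L]]]
      num <- as.numeric(m[4L])
      keep <- keep & switch(m[3L],
                            "<" = vals < num, "<=" = vals <= num,
                            ">" = vals > num, ">=" = vals >= num,
                            "==" = vals == num)
    }
  }
  keep[is.na(keep)] <- FALSE
  out <- rows[keep, , drop = FALSE]
  for (a in c("query", "year", "year_label")) attr(out, a) <- attr(rows, a)
  out
}
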