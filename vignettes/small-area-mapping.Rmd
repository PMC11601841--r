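---
title: "Small-area cancer mapping with arearisk: model, methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area cancer mapping with arearisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why smooth small-area rates

Direct age-adjusted rates computed from a handful of cases are dominated by
Poisson noise, and registry disclosure rules suppress them below a
case-count threshold — precisely in the rural and low-population areas where
local cancer-control planning most needs numbers.  `arearisk` replaces the
direct estimate with a model-based one that borrows strength from
neighboring areas and adjacent years, and reports its uncertainty honestly:
a posterior SD, an equal-tailed interval, an uncertainty class, and the
probability that the area's burden exceeds the state average.

## The model

For a single query — one cancer site, one outcome (incidence, late-stage
incidence or mortality), one stratum — the data are event counts $y_{iat}$
and person-years $n_{iat}$ per area $i$, age group $a$ and year $t$:

$$
y_{iat} \sim \mathrm{Poisson}(n_{iat}\,\lambda_{iat}), \qquad
\log \lambda_{iat} = \mu + \alpha_a + u_i + v_i + \gamma_t .
$$

* $u$ is the spatially structured effect with the intrinsic CAR (ICAR)
  prior, $p(u \mid \tau_u) \propto \tau_u^{(I-C)/2}
  \exp\!\big(-\tfrac{\tau_u}{2}\sum_{i\sim j}(u_i-u_j)^2\big)$, where
  $i \sim j$ runs over neighbor pairs of the area graph, $I$ is the number
  of areas and $C$ the number of connected components (the ICAR rank
  deficiency).  Together with the exchangeable $v_i \sim N(0, 1/\tau_v)$
  this is the BYM convolution.
* $\gamma$ is a first-order random walk over years with precision
  $\tau_g$ — the temporal borrowing.
* $\mu$ and the age effects $\alpha_a$ have $N(0, 10^2)$ priors; all
  precisions have Gamma(shape 1, rate 0.01) priors.  The proper, weakly
  informative hyperpriors keep the posterior proper despite the impropriety
  of the ICAR prior — the standard disease-mapping choice.

Identifiability: the ICAR and RW1 kernels are invariant to level shifts, so
the sampler enforces $\sum_a \alpha_a = 0$, $\sum_t \gamma_t = 0$ and
$\sum_{i \in c} u_i = 0$ per graph component by re-centering after each
block sweep, with $\mu$ absorbing the mean.  For a connected graph (and for
$\alpha$, $\gamma$ always) this leaves the likelihood exactly unchanged; for
disconnected geographies the per-component re-centering is the usual
centering-on-the-fly approximation, and the likelihood cache is rebuilt
after it.

The model family itself is this package's declared reading of "borrows
strength from neighboring areas and over time": a BYM convolution plus an
RW1 year effect, with no space–time interaction and no covariates.  The
choice is recorded in the fit metadata so downstream consumers can see
exactly which family produced an estimate.

## Stratification semantics

Queries follow the filter semantics of a mapping front end: each (site,
outcome, sex, race, year-range) combination is fitted separately, with no
cross-stratum pooling.  A stratum set to `"all"` pools by summing events and
person-years before fitting.  A year-range query collapses the years into
one period and drops the temporal term.  Sex-restricted sites are enforced
by `validate_query()`: prostate is male; breast and cervical are female; an
explicit incompatible sex is rejected in `strict` mode and corrected in
`coerce` mode, and a pooled `"all"` is always narrowed so that no null
stratum can be requested.

## The sampler

`fit_bym()` runs component-wise Gaussian random-walk Metropolis within
Gibbs, with the heavy loop in compiled code:

* every scalar block ($\mu$, each $\alpha_a$, each $u_i$, each $v_i$, each
  $\gamma_t$) is updated against its exact full conditional, using an
  incrementally maintained cache of $n_c e^{\eta_c}$ totals so one sweep
  costs $O(\text{cells})$;
* the precisions are conjugate: $\tau_u \sim \Gamma(a_0 + (I-C)/2,\,
  b_0 + \tfrac12\sum_{i\sim j}(u_i-u_j)^2)$ and analogously for $\tau_v$,
  $\tau_g$;
* one extra Metropolis move per sweep rescales the whole $u$ field,
  $u' = s\,u$ with a Jacobian term $(I-C)\log s$.  The $u$–$\tau_u$ pair is
  the classic slow-mixing direction of ICAR models, and this move is what
  keeps the $\tau_u$ chain mixing well;
* proposal SDs adapt toward 0.44 acceptance in batches of 50 during burn-in
  and are frozen afterwards, so the post-burn-in kernel is a fixed, valid
  MCMC kernel;
* defaults: 2 chains, 11,000 iterations, 1,000 burn-in, thinning 10 — 2,000
  retained draws.  Convergence is monitored by split-$\hat R$ on $\mu$, the
  precisions and three randomly chosen $u_i$; the command-line driver treats
  any monitored value above 1.2 as failure.

All randomness flows from one integer master seed through named streams
(`split_seed(seed, "chain1")`, `"truth"`, `"counts"`, ...), so adding a
consumer never perturbs another and every pipeline run is bit-reproducible.

## From draws to published measures

* **Age-adjusted rate.**  For draw $m$,
  $R_i^{(m)} = 10^5 \sum_a w_a \exp(\mu + \alpha_a + u_i + v_i + \gamma_t)$
  with standard-population weights $w_a$ ($\sum w_a = 1$) and $\gamma$ taken
  at the queried year (omitted for collapsed year-range fits).  The fixture
  default is a flat 4-group weight of 0.25 each; real deployments should
  substitute the US 2000 standard for their age grouping.  The scale is per
  100,000 person-years, the registry convention.
* **State reference.**  The state age-specific rate is the person-years-
  weighted mean of the area age-specific rates, then standardized with the
  same weights — so the reference equals the observable state rate in
  expectation, rather than an unweighted average of areas.
* **Risk (exceedance) probability.**  The fraction of retained draws with
  $R_i^{(m)} > R_{\text{state}}^{(m)}$; ties count as not exceeding
  (conservative).  It is invariant to any strictly monotone per-draw
  transform of both sides.
* **Point estimate and interval.**  Posterior mean and equal-tailed
  2.5/97.5 percentiles.
* **Hotspots.**  The top `ceiling(fraction * N)` rates (default fraction
  0.10, the "top 10%" rule); ties at the threshold are all flagged.
* **Uncertainty classes.**  Tertile split of the posterior SDs at the 1/3
  and 2/3 type-7 quantiles; boundary values take the lower class.  Fewer
  than three areas degenerate to all-`low` with a warning.
* **Suppression.**  The raw (direct) age-standardized rate is reported only
  when the area's total events reach the threshold (default 16, a common
  registry convention; the boundary count itself is released).  The modeled
  estimate is always available alongside — that is the point of the tool.

## The synthetic world

`simulate_registry()` generates the fixture every test runs on: a 10×10
queen-contiguity lattice (100 areas), four age groups with a colorectal-like
incidence gradient (2, 40, 120, 200 per 100,000 per year), five diagnosis
years, two sexes (±0.15 on the log scale) and two race groups (0 / +0.12),
per-area person-years log-uniform in [500, 50,000] per year with a
0.5/0.25/0.15/0.10 age split, an 85/15 race split and an even sex split.
The spatial effect is an exact ICAR draw (via the eigen-structure of the
graph Laplacian), centered per component and rescaled so the mean
theoretical marginal SD is 0.3; the year effect is a centered random walk
with innovation SD 0.05.  Late-stage counts are binomial thinnings of
incidence (probability 0.5); mortality is an independent Poisson outcome at
0.4 times the incidence rate.

The generating process deliberately equals the fitted model family, so
parameter-recovery tests are well-posed; a lognormal overdispersion
multiplier (`overdispersion_sd`) is provided as a misspecification switch.
What the generator does **not** emulate: irregular real-world adjacency,
age-by-area population structure differences, registry artifacts
(late-registration, geocoding error), or case-count correlation between
outcomes beyond the thinning link.  A green recovery test therefore
establishes correctness of the machinery under the stated world, not
robustness to real registry pathologies.

## Numerical and design choices

* **Contiguity.**  Queen contiguity is the default (corner contact counts),
  matching common disease-mapping practice; rook is available.  Polygon
  adjacency is decided by snapped shared vertices (tolerance `1e-8`
  coordinate units), which is exact for tessellated administrative
  geographies that share boundary vertices; self-intersecting rings are
  rejected naming the offending area.  Coordinates are treated as planar;
  adjacency needs only topology, so there is no CRS handling.
* **Disconnected maps** (islands) are accepted; constraints and the ICAR
  rank adjustment are applied per component.
* **Choropleth classing.**  Quantile breaks use type-7 quantiles (the R
  default); equal-interval splits the range evenly.  A value equal to a
  break falls in the *lower* bin, so bins are right-closed; fewer distinct
  values than classes falls back to equal-interval, constant input to a
  single bin.
* **Degenerate cells.**  Cells with zero person-years contribute nothing to
  the likelihood and are dropped before fitting.
* **Rate scale.**  Rates are per 100,000 population (person-years), the
  standard registry scale, and configurable through the `scale` argument.
* **Exports.**  The CSV is RFC 4180 with a fixed 18-column header, rates at
  one decimal and probabilities at three; the GeoJSON layer carries the same
  values at the same written precision (formatted identically, not
  `round()`ed) plus the style echo and a source note, so the two products
  never disagree and the map file re-parses to the identical adjacency.
* **PNG rendering** is a front-end concern and out of scope; the GeoJSON +
  style metadata is the deliverable a web map or GIS ingests directly.

## Limitations

* No space–time interaction, no ecological covariates, and no census-tract
  support — separate fits per stratum cannot pool information across
  strata.
* Exceedance probabilities are exchangeable comparisons with the state
  average, not cluster tests; a formal cluster-detection statistic is out of
  scope.
* The single-site Metropolis sampler is tuned for the fixture scale
  (hundreds of areas); thousands of areas would warrant block updates of
  $u$.
* Population density is not computed (it needs land-area measurements);
  person-years totals are the searchable proxy in the filter grammar.
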