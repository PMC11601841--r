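Package: arearisk
Title: Bayesian Small-Area Disease Mapping with Exceedance Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stabilized small-area cancer incidence, late-stage incidence and
    mortality rates from sparse registry counts.  Fits a Bayesian hierarchical
    spatio-temporal Poisson model with a BYM convolution prior (intrinsic CAR
    plus exchangeable area effects) and a first-order random-walk year effect
    by Metropolis-within-Gibbs MCMC, and converts posterior draws into direct
    age-standardized rates per 100,000 person-years, exceedance (risk)
    probabilities against the population-weighted state reference, hotspot
    flags, quantile-based uncertainty classes and suppression-aware raw-rate
    comparisons.  Includes a synthetic-registry generator with known ground
    truth, GeoJSON/edge-list geography handling, CSV and GeoJSON export with
    choropleth classification, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
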