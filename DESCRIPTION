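Package: dctmdr
Title: Dissipation-Corrected Targeted MD Profiles and Temperature-Boosted
    Langevin Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates free-energy and friction profiles along a
    one-dimensional reaction coordinate from ensembles of
    constant-velocity constrained pulling simulations, using the
    second-order cumulant expansion of the Jarzynski equality
    (dissipation-corrected targeted molecular dynamics). The resulting
    fields drive coarse-grained one-dimensional Langevin simulations with
    position-dependent friction, from which binding and unbinding rate
    constants are extracted. Rates at experimentally relevant (slow)
    timescales are reached by temperature boosting: simulating at
    elevated temperature on fields computed at the target temperature and
    extrapolating rates back via a Kramers-type Arrhenius relation.
    Includes a synthetic pulling-trace generator with known ground-truth
    fields for validation, jackknife error analysis, and work-distribution
    normality diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
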