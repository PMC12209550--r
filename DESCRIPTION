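Package: pilotopt
Title: Optimal Error Rates for Pilot and Definitive Trial Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian decision-theoretic design of two-stage trial programmes
    consisting of a pilot trial followed by a definitive trial, for two-arm
    parallel-group superiority comparisons with a normally distributed endpoint
    of known standard deviation. Constructs an exponential (constant absolute
    risk aversion) utility function over total sample size, change in mean
    outcome and treatment adoption from a small set of elicited quantities,
    computes expected utility under a normal prior on the treatment effect by
    Gauss-Hermite quadrature, and optimises per-arm sample sizes and test
    critical values for external pilots, internal pilots and programmes with
    heterogeneous pilot and definitive effects. Includes regret-based
    sensitivity analysis over prior and utility parameters, sweeps over the
    risk-attitude and effect-correlation parameters, and a seeded Monte Carlo
    programme simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    pracma,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    jsonlite,
    optparse
Config/testthat/edition: 3
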