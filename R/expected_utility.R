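# Cache of Gauss-Hermite rules keyed by node count (physicists' convention:
# sum w_i f(t_i) approximates integral of f(t) exp(-t^2) dt).
.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]]))
    .gh_cache[[key]] <- pracma::gaussHermite(nodes)
  .gh_cache[[key]]
}

# Values of the three terminal branches of a programme:
#   adopt          (G1 = 1, G2 = 1): n = n1 + n2, d = mu,  b = 0
#   definitive neg (G1 = 1, G2 = 0): n = n1 + n2, d = 0,   b = 1
#   pilot neg      (G1 = 0)        : n = n1,      d = 0,   b = 1
# The sample-size attribute is the sum of the per-arm stage sizes.
terminal_values <- function(design, utility, mu) {
  w <- utility$weights
  list(adopt = w$kd * mu + w$kn * (design$n1 + design$n2),
       main_neg = w$kn * (design$n1 + design$n2) + w$kb,
       pilot_neg = w$kn * design$n1 + w$kb)
}

#' Probabilities of the three terminal programme branches
#'
#' Given the true definitive effect `mu`, returns
#' `Pr[G1 = 1, G2 = 1 | mu]`, `Pr[G1 = 1, G2 = 0 | mu]` and
#' `Pr[G1 = 0 | mu]`, where `Gi` indicates a positive stage-`i` test. For an
#' external pilot the stage statistics are independent given `mu` and the
#' joint probabilities factor through `Pr[G1 = 1 | mu]`; for an internal
#' pilot they are computed from the bivariate normal joint law of the pilot
#' and pooled means; under a bivariate (heterogeneous-effect) prior the
#' pilot probability uses the conditional sampling distribution of `x1`
#' given `mu` (see [pilot_sampling_given_mu()]).
#'
#' @param design A `programme_design`.
#' @param mu Numeric vector of true definitive effects.
#' @param scenario A `trial_scenario`.
#' @return A list of vectors `p11`, `p10`, `p0` summing to 1 elementwise.
#' @export
branch_probabilities <- function(design, mu, scenario) {
  stopifnot(inherits(design, "programme_design"),
            inherits(scenario, "trial_scenario"))
  sg <- scenario$sigma
  if (design$pilot_type == "internal") {
    p11 <- internal_joint_power(design, mu, sg)
    p1 <- stage_power(design$n1, design$c1, mu, sg)
  } else {
    p1 <- if (inherits(scenario$prior, "bivariate_effect_prior")) {
      heterogeneous_pilot_power(scenario$prior, mu, design$n1, design$c1, sg)
    } else {
      stage_power(design$n1, design$c1, mu, sg)
    }
    p2 <- stage_power(design$n2, design$c2, mu, sg)
    p11 <- p1 * p2
  }
  list(p11 = p11, p10 = p1 - p11, p0 = 1 - p1)
}

#' Expected utility of a programme conditional on the true effect
#'
#' Probability-weighted utility of the three terminal branches (adopt the
#' intervention; retain control after a negative definitive test; retain
#' control after a negative pilot test), with the branch probabilities of
#' [branch_probabilities()]. Exact in each exponential branch of the
#' utility; no integration is involved.
#'
#' @inheritParams branch_probabilities
#' @return Numeric vector of conditional expected utilities, one per `mu`.
#' @export
conditional_eu <- function(design, mu, scenario) {
  p <- branch_probabilities(design, mu, scenario)
  rho <- scenario$utility$rho
  v <- terminal_values(design, scenario$utility, mu)
  p$p11 * value_to_utility(v$adopt, rho) +
    p$p10 * value_to_utility(v$main_neg, rho) +
    p$p0 * value_to_utility(v$pilot_neg, rho)
}

# Integrate a function f(mu) against the N(m, s^2) prior by Gauss-Hermite
# quadrature with the change of variable mu = m + sqrt(2)*s*t.
prior_integral <- function(f, m, s, nodes) {
  if (s == 0) return(f(m))
  gh <- gh_rule(nodes)
  sum(gh$w * f(m + sqrt(2) * s * gh$x)) / sqrt(pi)
}

#' Prior expected utility of a programme design
#'
#' Integrates the conditional expected utility over the effect prior by
#' Gauss-Hermite quadrature. Dispatches on the design's pilot type and the
#' prior's class: external pilot with a univariate prior (the base case),
#' internal pilot ([expected_utility_internal()]), or external pilot with a
#' bivariate heterogeneous-effect prior
#' ([expected_utility_heterogeneous()]).
#'
#' @param design A `programme_design`.
#' @param scenario A `trial_scenario`.
#' @return Scalar expected utility. With `rho > 0` utilities lie in
#'   `(-Inf, 1)`; the worked example gives positive values around 0.43.
#' @export
#' @examples
#' sc <- ok_diabetes_scenario()
#' d <- design_from_alpha(41, 0.39, 146, 0.041, sc$sigma)
#' expected_utility(d, sc)
expected_utility <- function(design, scenario) {
  stopifnot(inherits(design, "programme_design"),
            inherits(scenario, "trial_scenario"))
  if (design$pilot_type == "internal")
    return(expected_utility_internal(design, scenario))
  if (inherits(scenario$prior, "bivariate_effect_prior"))
    return(expected_utility_heterogeneous(design, scenario))
  prior_integral(function(mu) conditional_eu(design, mu, scenario),
                 scenario$prior$m, scenario$prior$s, scenario$nodes)
}

#' Quadrature convergence check
#'
#' Recomputes the expected utility with twice the scenario's node count and
#' reports both values and their difference. Useful when adapting the
#' package to scenarios with priors much tighter or wider than the bundled
#' example.
#'
#' @inheritParams expected_utility
#' @return List with `eu`, `eu_doubled`, `delta`, `nodes`.
#' @export
eu_convergence <- function(design, scenario) {
  e1 <- expected_utility(design, scenario)
  sc2 <- scenario
  sc2$nodes <- 2L * scenario$nodes
  e2 <- expected_utility(design, sc2)
  list(eu = e1, eu_doubled = e2, delta = e2 - e1, nodes = scenario$nodes)
}
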