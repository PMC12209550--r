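#' Normal prior on the treatment effect
#'
#' A subjective prior `mu ~ N(m, s^2)` expressing the decision-maker's belief
#' about the true mean difference before any data. It is used only to weight
#' the frequentist operating characteristics when computing expected utility,
#' never in the analysis of the trial data. `s = 0` is allowed and denotes a
#' point mass at `m`.
#'
#' @param m Prior mean (effect units).
#' @param s Prior standard deviation (effect units, `>= 0`).
#' @return An object of class `effect_prior`.
#' @export
effect_prior <- function(m, s) {
  stopifnot(is.numeric(m), is.numeric(s), length(m) == 1L, length(s) == 1L)
  if (s < 0) stop("prior SD must be non-negative")
  structure(list(m = m, s = s), class = "effect_prior")
}

#' Bivariate normal prior for heterogeneous pilot and definitive effects
#'
#' Allows the true effect in the pilot trial, `mu_p`, to differ from the true
#' effect in the definitive trial, `mu`:
#' `(mu_p, mu) ~ N((mp, m), [[sp^2, tau*sp*s], [tau*sp*s, s^2]])`.
#' `tau` is the prior correlation between the two effects; `tau = 1` with
#' matching marginals recovers the homogeneous (common-effect) model.
#'
#' @param mp,sp Pilot-effect prior mean and SD.
#' @param m,s Definitive-effect prior mean and SD.
#' @param tau Correlation in `[-1, 1]`.
#' @return An object of class `bivariate_effect_prior` (also inherits
#'   `effect_prior`; the `m`, `s` elements are the definitive-effect
#'   marginal, which is the prior integrated over).
#' @export
bivariate_effect_prior <- function(mp, sp, m, s, tau) {
  stopifnot(sp >= 0, s >= 0, abs(tau) <= 1)
  structure(list(m = m, s = s, mp = mp, sp = sp, tau = tau),
            class = c("bivariate_effect_prior", "effect_prior"))
}

#' Design scenario: endpoint, prior, utility and quadrature settings
#'
#' Assembles everything needed to evaluate a programme design: the endpoint
#' SD, the effect prior (univariate or bivariate), the utility parameters,
#' the alternative effect `mu_star` at which operating characteristics are
#' reported, and the number of Gauss-Hermite quadrature nodes used for the
#' prior integral.
#'
#' @param sigma Outcome SD (> 0), common to both arms.
#' @param prior An [effect_prior()] or [bivariate_effect_prior()].
#' @param utility A [utility_params()] object.
#' @param mu_star Alternative effect at which type II error rates are
#'   reported (cosmetic to the optimisation itself).
#' @param nodes Number of quadrature nodes (>= 5). The default 151 changes by
#'   less than 1e-9 on doubling in the bundled worked example; see
#'   [eu_convergence()].
#' @return An object of class `trial_scenario`.
#' @export
scenario <- function(sigma, prior, utility, mu_star, nodes = 151L) {
  stopifnot(sigma > 0, inherits(prior, "effect_prior"),
            inherits(utility, "utility_params"), nodes >= 5)
  structure(list(sigma = sigma, prior = prior, utility = utility,
                 mu_star = mu_star, nodes = as.integer(nodes)),
            class = "trial_scenario")
}

#' Programme design: per-arm sizes and critical values
#'
#' The decision variable `z = (n1, c1, n2, c2)`: per-arm sample sizes and
#' critical values for the pilot (stage 1) and definitive (stage 2) tests.
#' Critical values are the primitive representation; the equivalent
#' `(alpha1, alpha2)` view requires `sigma` (see [design_from_alpha()] and
#' [operating_characteristics()]). A stage with `n = 0` degenerates to
#' "always proceed" (`alpha = 1`, `beta = 0`); its critical value is stored
#' as `-Inf`.
#'
#' For an internal pilot (`pilot_type = "internal"`) the second test is
#' applied to the pooled mean difference
#' `xt = (n1*x1 + n2*x2) / (n1 + n2)`, so `c2` lives on the pooled scale.
#'
#' @param n1,n2 Per-arm sample sizes (non-negative integers).
#' @param c1,c2 Critical values (mean-difference scale; `-Inf`/`Inf`
#'   allowed).
#' @param pilot_type `"external"` or `"internal"`.
#' @return An object of class `programme_design`.
#' @export
programme_design <- function(n1, c1, n2, c2, pilot_type = "external") {
  pilot_type <- match.arg(pilot_type, c("external", "internal"))
  stopifnot(n1 >= 0, n2 >= 0, n1 == round(n1), n2 == round(n2))
  if (pilot_type == "internal" && n1 == 0)
    stop("an internal pilot requires n1 >= 1")
  if (n1 == 0) c1 <- -Inf
  if (n2 == 0) c2 <- -Inf
  structure(list(n1 = as.integer(n1), c1 = c1,
                 n2 = as.integer(n2), c2 = c2,
                 pilot_type = pilot_type),
            class = "programme_design")
}

#' Construct a design from stage alpha levels
#'
#' Convenience wrapper mapping `(alpha1, alpha2)` to critical values given
#' `sigma`. For internal pilots `alpha2` is defined on the null distribution
#' of the pooled statistic, i.e. `c2 = sigma*sqrt(2/(n1+n2))*qnorm(1-alpha2)`.
#'
#' @inheritParams programme_design
#' @param alpha1,alpha2 One-sided stage type I error rates in `(0, 1]`.
#' @param sigma Outcome SD.
#' @return A `programme_design`.
#' @export
design_from_alpha <- function(n1, alpha1, n2, alpha2, sigma,
                              pilot_type = "external") {
  pilot_type <- match.arg(pilot_type, c("external", "internal"))
  c1 <- if (n1 == 0) -Inf else critical_value(n1, alpha1, sigma)
  c2 <- if (n2 == 0) -Inf else if (pilot_type == "internal")
    critical_value(n1 + n2, alpha2, sigma) else
    critical_value(n2, alpha2, sigma)
  programme_design(n1, c1, n2, c2, pilot_type)
}

#' Operating characteristics of a programme design
#'
#' Stage-level and programme-level one-sided error rates at the null and at
#' the scenario's stated alternative `mu_star`. For external pilots the
#' programme rates compose as `alpha_t = alpha1*alpha2`,
#' `beta_t = beta1 + (1-beta1)*beta2`; for internal pilots the stages share
#' data, so `alpha_t = Pr[x1 > c1, xt > c2 | mu = 0]` (and `beta_t` its
#' counterpart at `mu_star`) are computed from the bivariate normal joint
#' distribution of `(x1, xt)`.
#'
#' @param design A `programme_design`.
#' @param scenario A `trial_scenario` (only `sigma` and `mu_star` are used).
#' @return A list of class `programme_oc` with elements `alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `alpha_t`, `beta_t`, `mu_star`.
#' @export
operating_characteristics <- function(design, scenario) {
  stopifnot(inherits(design, "programme_design"),
            inherits(scenario, "trial_scenario"))
  sg <- scenario$sigma; ms <- scenario$mu_star
  a1 <- implied_alpha(design$n1, design$c1, sg)
  b1 <- if (design$n1 == 0) 0 else
    1 - stage_power(design$n1, design$c1, ms, sg)
  if (design$pilot_type == "external") {
    a2 <- implied_alpha(design$n2, design$c2, sg)
    b2 <- if (design$n2 == 0) 0 else
      1 - stage_power(design$n2, design$c2, ms, sg)
    ov <- overall_rates(a1, b1, a2, b2)
    at <- ov$alpha_t; bt <- ov$beta_t
  } else {
    nt <- design$n1 + design$n2
    a2 <- implied_alpha(nt, design$c2, sg)
    b2 <- 1 - stage_power(nt, design$c2, ms, sg)
    at <- internal_joint_power(design, 0, sg)
    bt <- 1 - internal_joint_power(design, ms, sg)
  }
  structure(list(alpha1 = a1, beta1 = b1, alpha2 = a2, beta2 = b2,
                 alpha_t = at, beta_t = bt, mu_star = ms,
                 pilot_type = design$pilot_type),
            class = "programme_oc")
}

#' @export
print.programme_design <- function(x, ...) {
  cat(sprintf("Programme design (%s pilot):\n", x$pilot_type))
  cat(sprintf("  stage 1: n1 = %d per arm, c1 = %.4g\n", x$n1, x$c1))
  lab <- if (x$pilot_type == "internal") "pooled c2" else "c2"
  cat(sprintf("  stage 2: n2 = %d per arm, %s = %.4g\n", x$n2, lab, x$c2))
  invisible(x)
}

#' @export
print.programme_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics at mu* = %g:\n", x$mu_star))
  cat(sprintf("  stage 1: alpha1 = %.3f, beta1 = %.3f\n", x$alpha1, x$beta1))
  cat(sprintf("  stage 2: alpha2 = %.3f, beta2 = %.3f\n", x$alpha2, x$beta2))
  cat(sprintf("  overall: alpha_t = %.3f, beta_t = %.3f\n",
              x$alpha_t, x$beta_t))
  invisible(x)
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat("Trial programme scenario\n")
  cat(sprintf("  endpoint SD: sigma = %g\n", x$sigma))
  if (inherits(x$prior, "bivariate_effect_prior")) {
    cat(sprintf("  prior: mu_p ~ N(%g, %g^2), mu ~ N(%g, %g^2), tau = %g\n",
                x$prior$mp, x$prior$sp, x$prior$m, x$prior$s, x$prior$tau))
  } else {
    cat(sprintf("  prior: mu ~ N(%g, %g^2)\n", x$prior$m, x$prior$s))
  }
  cat(sprintf("  alternative for OCs: mu* = %g\n", x$mu_star))
  cat(sprintf("  quadrature nodes: %d\n", x$nodes))
  print(x$utility)
  invisible(x)
}
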