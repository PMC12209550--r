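#' Monte Carlo simulation of a trial programme
#'
#' Simulates whole programme runs: the true effect is drawn from the prior
#' (or fixed at `fixed_mu`), stage statistics are drawn from their sampling
#' distributions, the decision rules are applied, and the realised utilities
#' of the terminal outcomes are averaged. This is an independent execution
#' path used to cross-check the analytic expected-utility and
#' operating-characteristic computations; it shares only the terminal
#' utility definitions with them.
#'
#' For an external pilot, `x1` and `x2` are independent normal means given
#' the true effect(s); under a bivariate (heterogeneous) prior the pilot
#' statistic centres on the drawn pilot effect `mu_p`. For an internal
#' pilot, the pooled statistic `xt = (n1*x1 + n2*x2)/(n1 + n2)` is tested at
#' stage 2. A stage with `n = 0` always proceeds.
#'
#' @param design A `programme_design`.
#' @param scenario A `trial_scenario`.
#' @param n_sims Number of simulated programmes (>= 1).
#' @param seed Integer seed; identical seed and parameters give identical
#'   results.
#' @param fixed_mu Optional scalar: condition on this true effect instead of
#'   drawing from the prior (under a bivariate prior, `mu_p` is still drawn
#'   from its conditional given `mu = fixed_mu`). With `fixed_mu = 0` the
#'   empirical final-positive rate estimates `alpha_t`; at `mu_star` it
#'   estimates `1 - beta_t`.
#' @return A list of class `simulation_result`: `mean_utility`, `se`
#'   (sample SD / sqrt(n_sims)), `branch_freq` (adopt / definitive-negative
#'   / pilot-negative), `final_positive_rate`, `n_sims`, `seed`.
#' @export
simulate_programme <- function(design, scenario, n_sims, seed,
                               fixed_mu = NULL) {
  stopifnot(inherits(design, "programme_design"),
            inherits(scenario, "trial_scenario"), n_sims >= 1)
  sg <- scenario$sigma; pr <- scenario$prior
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  bivar <- inherits(pr, "bivariate_effect_prior")
  if (is.null(fixed_mu)) {
    mu <- stats::rnorm(n_sims, pr$m, pr$s)
  } else {
    mu <- rep(fixed_mu, n_sims)
  }
  if (bivar) {
    if (pr$s == 0 && pr$tau != 0)
      stop("conditional pilot effect undefined: s = 0 with tau != 0")
    slope <- if (pr$tau == 0) 0 else pr$tau * pr$sp / pr$s
    mup <- stats::rnorm(n_sims, pr$mp + slope * (mu - pr$m),
                        sqrt(max(0, 1 - pr$tau^2)) * pr$sp)
  } else {
    mup <- mu
  }
  x1 <- if (design$n1 > 0)
    stats::rnorm(n_sims, mup, sg * sqrt(2 / design$n1)) else rep(Inf, n_sims)
  g1 <- x1 > design$c1
  if (design$pilot_type == "internal") {
    x2 <- stats::rnorm(n_sims, mu, sg * sqrt(2 / max(design$n2, 1)))
    xt <- if (design$n2 > 0)
      (design$n1 * x1 + design$n2 * x2) / (design$n1 + design$n2) else x1
    g2 <- xt > design$c2
  } else {
    x2 <- if (design$n2 > 0)
      stats::rnorm(n_sims, mu, sg * sqrt(2 / design$n2)) else rep(Inf, n_sims)
    g2 <- x2 > design$c2
  }
  v <- terminal_values(design, scenario$utility, mu)
  val <- ifelse(g1 & g2, v$adopt, ifelse(g1, v$main_neg, v$pilot_neg))
  u <- value_to_utility(val, scenario$utility$rho)
  freq <- c(adopt = mean(g1 & g2), main_neg = mean(g1 & !g2),
            pilot_neg = mean(!g1))
  structure(list(mean_utility = mean(u),
                 se = stats::sd(u) / sqrt(n_sims),
                 branch_freq = freq,
                 final_positive_rate = unname(freq["adopt"]),
                 n_sims = n_sims, seed = as.integer(seed)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulated programme (%d runs, seed %d)\n", x$n_sims, x$seed))
  cat(sprintf("  mean utility: %.5f (SE %.2g)\n", x$mean_utility, x$se))
  cat(sprintf("  branches: adopt %.3f, definitive-negative %.3f, ",
              x$branch_freq["adopt"], x$branch_freq["main_neg"]))
  cat(sprintf("pilot-negative %.3f\n", x$branch_freq["pilot_neg"]))
  invisible(x)
}
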