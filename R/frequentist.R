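#' Stage critical value for a one-sided z-test
#'
#' Each stage compares the observed mean difference `x` between arms to a
#' critical value `c`, rejecting (a "positive" result) when `x > c`. With a
#' known common outcome SD `sigma` and `n` participants per arm,
#' `x | mu ~ N(mu, 2 sigma^2 / n)`, so the critical value attaining a
#' one-sided type I error rate `alpha` is
#' `c = sigma * sqrt(2/n) * qnorm(1 - alpha)`.
#'
#' `alpha = 1` returns `-Inf` (the stage always proceeds, the "no test"
#' convention); a stage with `n = 0` is treated the same way by the
#' programme-level functions.
#'
#' @param n Per-arm sample size (>= 1 unless `alpha = 1`).
#' @param alpha One-sided type I error rate in `(0, 1]`.
#' @param sigma Outcome standard deviation (> 0).
#' @return Critical value on the mean-difference scale.
#' @export
critical_value <- function(n, alpha, sigma) {
  stopifnot(sigma > 0)
  if (any(alpha <= 0) || any(alpha > 1)) stop("alpha must be in (0, 1]")
  ifelse(alpha == 1, -Inf, sigma * sqrt(2 / n) * stats::qnorm(1 - alpha))
}

#' Null rejection probability implied by a critical value
#'
#' Inverse of [critical_value()]: the one-sided type I error rate of the test
#' `x > c` at per-arm size `n`.
#'
#' @inheritParams critical_value
#' @param c Critical value (mean-difference scale; `-Inf` gives 1).
#' @return Probability in `[0, 1]`.
#' @export
implied_alpha <- function(n, c, sigma) {
  stopifnot(sigma > 0)
  ifelse(is.infinite(c) & c < 0, 1,
         ifelse(n == 0, 1, 1 - stats::pnorm(c / (sigma * sqrt(2 / n)))))
}

#' Power of a stage test at a given true effect
#'
#' `Pr[x > c | mu]` for the stage statistic `x ~ N(mu, 2 sigma^2 / n)`.
#' A stage with `n = 0` (or `c = -Inf`) always proceeds, so its power is 1.
#'
#' @param n Per-arm sample size.
#' @param c Critical value.
#' @param mu True mean difference.
#' @param sigma Outcome standard deviation.
#' @return Probability; vectorised over `mu`.
#' @export
stage_power <- function(n, c, mu, sigma) {
  stopifnot(sigma > 0)
  if (n == 0 || (is.infinite(c) && c < 0)) return(rep(1, length(mu)))
  1 - stats::pnorm((c - mu) / (sigma * sqrt(2 / n)))
}

#' Type II error rate at a stated alternative for a given alpha
#'
#' Convenience composition: the critical value attaining `alpha` is computed
#' first, then the type II error `beta = Pr[x <= c | mu]` at the alternative.
#'
#' @inheritParams critical_value
#' @param mu Alternative effect.
#' @return `beta` in `[0, 1]`.
#' @export
beta_at_alpha <- function(n, alpha, mu, sigma) {
  1 - stage_power(n, critical_value(n, alpha, sigma), mu, sigma)
}

#' Programme-level error rates from stage error rates
#'
#' The programme rejects overall only if both stages reject, and the stage
#' statistics are independent given `mu` (external pilot), so
#' `alpha_t = alpha1 * alpha2` and `beta_t = beta1 + (1 - beta1) * beta2`.
#'
#' @param alpha1,beta1,alpha2,beta2 Stage error rates in `[0, 1]`.
#' @return List with `alpha_t` and `beta_t`.
#' @export
#' @examples
#' overall_rates(0.39, 0.110, 0.041, 0.132)  # alpha_t ~ 0.016
overall_rates <- function(alpha1, beta1, alpha2, beta2) {
  stopifnot(all(c(alpha1, beta1, alpha2, beta2) >= 0),
            all(c(alpha1, beta1, alpha2, beta2) <= 1))
  list(alpha_t = alpha1 * alpha2,
       beta_t = beta1 + (1 - beta1) * beta2)
}

#' Smallest per-arm sample size attaining a target power
#'
#' Solves `stage_power(n, critical_value(n, alpha, sigma), mu, sigma) >=
#' power` for integer `n`, returning the ceiling of the closed-form
#' continuous solution `n = 2 sigma^2 (z_{1-alpha} + z_{power})^2 / mu^2`
#' (checked and adjusted by +/- 1 so that `n - 1` falls short).
#'
#' @param power Target power, `alpha < power < 1`.
#' @param alpha One-sided type I error rate.
#' @param mu Alternative effect (non-zero, same sign as the rejection
#'   direction).
#' @param sigma Outcome standard deviation.
#' @return Integer per-arm sample size.
#' @export
#' @examples
#' solve_sample_size(0.9, 0.025, 0.5, 1.5)  # 190
solve_sample_size <- function(power, alpha, mu, sigma) {
  stopifnot(sigma > 0)
  if (mu <= 0) stop("mu must be positive for a superiority test")
  if (!(alpha > 0 && alpha < power && power < 1))
    stop("need 0 < alpha < power < 1")
  n <- ceiling(2 * sigma^2 *
                 (stats::qnorm(1 - alpha) + stats::qnorm(power))^2 / mu^2)
  # guard against floating-point edge cases around the ceiling
  while (n > 1 &&
         1 - beta_at_alpha(n - 1, alpha, mu, sigma) >= power) n <- n - 1
  while (1 - beta_at_alpha(n, alpha, mu, sigma) < power) n <- n + 1
  as.integer(n)
}
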