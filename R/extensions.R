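# Vectorised upper-orthant probability P(X > h, Y > k) for a standard
# bivariate normal pair with correlation r (scalar). Used in the internal-
# pilot expected utility, where it is evaluated at every quadrature node of
# every objective evaluation, so it must be fast as well as accurate;
# mvtnorm::pmvnorm is the (non-vectorised) reference it is tested against.
#
# Method: reduce to r >= 0 via P(X>h, Y>k; r) = P(X>h) - P(X>h, -Y>-k; -r),
# then integrate the conditional decomposition
#   P = int_h^Inf phi(x) * Pnorm_bar((k - r x)/sqrt(1-r^2)) dx
# by Gauss-Legendre on the sub-interval where the sigmoid factor is neither
# ~0 nor ~1 (the remaining piece on the ~1 side is a closed-form normal
# probability). Truncation at 8.5 conditional SDs keeps the absolute error
# below 1e-12 across |r| <= 1 - 1e-12; r beyond that is treated as
# comonotone, P = min(Pnorm_bar(h), Pnorm_bar(k)).
.gl_cache <- new.env(parent = emptyenv())

gl_rule <- function(nodes = 64L) {
  key <- as.character(nodes)
  if (is.null(.gl_cache[[key]])) {
    g <- pracma::gaussLegendre(nodes, 0, 1)
    .gl_cache[[key]] <- list(x = g$x, w = g$w)
  }
  .gl_cache[[key]]
}

bvn_upper <- function(h, k, r) {
  stopifnot(length(r) == 1L, abs(r) <= 1)
  nn <- max(length(h), length(k))
  h <- rep_len(h, nn); k <- rep_len(k, nn)
  if (r < 0) return(pmax(0, stats::pnorm(h, lower.tail = FALSE) -
                            bvn_upper(h, -k, -r)))
  if (r > 1 - 1e-12)
    return(pmin(stats::pnorm(h, lower.tail = FALSE),
                stats::pnorm(k, lower.tail = FALSE)))
  if (r == 0)
    return(stats::pnorm(h, lower.tail = FALSE) *
             stats::pnorm(k, lower.tail = FALSE))
  out <- numeric(nn)
  # infinite bounds degenerate to univariate tails
  hi_inf <- h == Inf | k == Inf
  h_ninf <- h == -Inf & !hi_inf
  k_ninf <- k == -Inf & !hi_inf & !h_ninf
  out[h_ninf] <- stats::pnorm(k[h_ninf], lower.tail = FALSE)
  out[k_ninf] <- stats::pnorm(h[k_ninf], lower.tail = FALSE)
  fin <- !(hi_inf | h_ninf | k_ninf)
  if (any(fin)) {
    hf <- h[fin]; kf <- k[fin]
    s <- sqrt(1 - r^2)
    lo <- pmax(hf, -9)
    # sigmoid factor ~0 below a, ~1 above b
    a <- (kf - 8.5 * s) / r
    b <- (kf + 8.5 * s) / r
    # middle panel [l2, u2]: numeric quadrature
    l2 <- pmax(lo, a); u2 <- pmin(9, b)
    width <- pmax(u2 - l2, 0)
    gl <- gl_rule()
    xs <- outer(width, gl$x) + l2          # n x nodes
    gx <- stats::pnorm((kf - r * xs) / s, lower.tail = FALSE)
    mid <- as.numeric((stats::dnorm(xs) * gx) %*% gl$w) * width
    # upper panel [max(lo, b), 9]: sigmoid ~ 1, closed form
    l3 <- pmax(lo, b)
    upper <- pmax(stats::pnorm(9) - stats::pnorm(pmin(l3, 9)), 0)
    out[fin] <- pmin(pmax(mid + upper, 0), 1)
  }
  out
}

#' Joint distribution of the pilot and pooled mean differences
#'
#' For an internal pilot the definitive analysis pools the pilot data:
#' `xt = (n1*x1 + n2*x2) / (n1 + n2)`. Conditional on the true effect `mu`,
#' `(x1, xt)` are bivariate normal with common mean `mu`, variances
#' `2*sigma^2/n1` and `2*sigma^2/(n1+n2)`, and covariance
#' `2*sigma^2/(n1+n2)` (the pooled mean's variance), giving correlation
#' `sqrt(n1/(n1+n2))`.
#'
#' @param n1 Per-arm pilot size (>= 1).
#' @param n2 Per-arm stage-2 size (>= 0).
#' @param sigma Outcome SD.
#' @param mu True effect.
#' @return List with `mean` (2-vector), `cov` (2x2 matrix) and `corr`.
#' @export
internal_joint <- function(n1, n2, sigma, mu) {
  if (n1 < 1) stop("an internal pilot requires n1 >= 1")
  stopifnot(n2 >= 0, sigma > 0)
  v1 <- 2 * sigma^2 / n1
  vt <- 2 * sigma^2 / (n1 + n2)
  list(mean = c(mu, mu),
       cov = matrix(c(v1, vt, vt, vt), 2, 2),
       corr = sqrt(n1 / (n1 + n2)))
}

# P(x1 > c1, xt > c2 | mu) for an internal design; vectorised over mu.
internal_joint_power <- function(design, mu, sigma) {
  j <- internal_joint(design$n1, design$n2, sigma, 0)
  s1 <- sqrt(j$cov[1, 1]); st <- sqrt(j$cov[2, 2])
  bvn_upper((design$c1 - mu) / s1, (design$c2 - mu) / st, j$corr)
}

#' Expected utility of an internal-pilot programme
#'
#' As [expected_utility()], but with the stage-2 test applied to the pooled
#' mean `xt`, so the branch probabilities come from the bivariate normal
#' joint law of `(x1, xt)` given `mu` (see [internal_joint()]) rather than
#' factorising across independent stages. Reduces to the external
#' single-stage case when `n2 = 0` and `c2 = c1`.
#'
#' @inheritParams expected_utility
#' @return Scalar expected utility.
#' @export
expected_utility_internal <- function(design, scenario) {
  stopifnot(design$pilot_type == "internal",
            !inherits(scenario$prior, "bivariate_effect_prior"))
  prior_integral(function(mu) conditional_eu(design, mu, scenario),
                 scenario$prior$m, scenario$prior$s, scenario$nodes)
}

#' Sampling distribution of the pilot estimate given the definitive effect
#'
#' Under the heterogeneous-effect model the pilot estimate `x1` no longer
#' centres on the definitive effect `mu`. Marginalising the pilot effect
#' `mu_p` out of the bivariate prior gives
#' `x1 | mu ~ N(mp + tau*(sp/s)*(mu - m), (1 - tau^2)*sp^2 + 2*sigma^2/n1)`:
#' the conditional prior uncertainty about `mu_p` inflates the pilot
#' sampling variance.
#'
#' @param prior A [bivariate_effect_prior()].
#' @param mu True definitive effect (vectorised).
#' @param n1 Per-arm pilot size (>= 1).
#' @param sigma Outcome SD.
#' @return List with vectors `mean` and scalar `sd`.
#' @export
pilot_sampling_given_mu <- function(prior, mu, n1, sigma) {
  stopifnot(inherits(prior, "bivariate_effect_prior"), n1 >= 1, sigma > 0)
  if (prior$s == 0 && prior$tau != 0)
    stop("conditional distribution undefined: s = 0 with tau != 0")
  slope <- if (prior$tau == 0) 0 else prior$tau * prior$sp / prior$s
  list(mean = prior$mp + slope * (mu - prior$m),
       sd = sqrt((1 - prior$tau^2) * prior$sp^2 + 2 * sigma^2 / n1))
}

# P(x1 > c1 | mu) under the heterogeneous model; vectorised over mu.
heterogeneous_pilot_power <- function(prior, mu, n1, c1, sigma) {
  if (n1 == 0 || (is.infinite(c1) && c1 < 0)) return(rep(1, length(mu)))
  cond <- pilot_sampling_given_mu(prior, mu, n1, sigma)
  1 - stats::pnorm((c1 - cond$mean) / cond$sd)
}

#' Expected utility under heterogeneous pilot and definitive effects
#'
#' External-pilot expected utility when the true pilot effect `mu_p` may
#' differ from the definitive effect `mu`, linked by a bivariate normal
#' prior with correlation `tau`. The pilot pass probability uses
#' [pilot_sampling_given_mu()]; the definitive-stage probabilities and the
#' adopt-branch payoff are driven by `mu` (the quantity of ultimate
#' interest), and the outer integral is over the marginal prior of `mu`.
#' With `tau = 1` and matching marginals this equals [expected_utility()]
#' under the corresponding univariate prior.
#'
#' @inheritParams expected_utility
#' @return Scalar expected utility.
#' @export
expected_utility_heterogeneous <- function(design, scenario) {
  stopifnot(design$pilot_type == "external",
            inherits(scenario$prior, "bivariate_effect_prior"))
  prior_integral(function(mu) conditional_eu(design, mu, scenario),
                 scenario$prior$m, scenario$prior$s, scenario$nodes)
}
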