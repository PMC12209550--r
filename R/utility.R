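#' Elicited inputs for the value function
#'
#' Bundles the three elicited quantities that determine the weights of the
#' additive value function over the attributes (total sample size `n`, change
#' in mean outcome `d`, control-retention indicator `b`):
#'
#' * `d_bar` -- the change in mean outcome that would justify increasing the
#'   total sample size from 0 to `n_star` participants (the sampling cost,
#'   in effect units per `n_star` participants);
#' * `d_hat` -- the change in mean outcome that would justify switching from
#'   the control to the new intervention (the treatment cost, in effect
#'   units); negative values express a non-inferiority framing;
#' * `n_star` -- the reference sample size used in the sampling-cost
#'   elicitation (participants).
#'
#' @param d_bar Positive scalar, effect units.
#' @param d_hat Scalar, effect units (any sign).
#' @param n_star Positive scalar, participants.
#' @return An object of class `elicitation`.
#' @seealso [derive_weights()]
#' @export
#' @examples
#' elicitation(d_bar = 0.005, d_hat = 0.3, n_star = 50)
elicitation <- function(d_bar, d_hat, n_star) {
  stopifnot(is.numeric(d_bar), length(d_bar) == 1L,
            is.numeric(d_hat), length(d_hat) == 1L,
            is.numeric(n_star), length(n_star) == 1L)
  if (!is.finite(d_bar) || d_bar <= 0)
    stop("invalid elicitation: d_bar must be a positive finite number")
  if (!is.finite(n_star) || n_star <= 0)
    stop("invalid elicitation: n_star must be a positive finite number")
  structure(list(d_bar = d_bar, d_hat = d_hat, n_star = n_star),
            class = "elicitation")
}

#' Derive value-function weights from elicited quantities
#'
#' Converts the elicited quantities into the weights `(kd, kn, kb)` of the
#' additive value function `v(n, d, b) = kn*n + kd*d + kb*b`:
#' \deqn{k_d = 1 / (1 + \hat{d} - \bar{d}/n^*), \quad
#'       k_n = -k_d \bar{d}/n^*, \quad
#'       k_b = 1 - k_d - k_n \hat{d}.}
#' `kn` is negative (each participant costs value), `kd` rewards improvement
#' in the mean outcome, and `kb` is the value of retaining the control
#' treatment (implicitly, of avoiding the cost of switching).
#'
#' @param e An [elicitation()] object.
#' @return An object of class `trial_weights`: list with elements `kd`, `kn`,
#'   `kb`.
#' @export
#' @examples
#' derive_weights(elicitation(0.005, 0.3, 50))  # kd = 0.769, kn = -7.69e-5
derive_weights <- function(e) {
  stopifnot(inherits(e, "elicitation"))
  kd <- 1 / (1 + e$d_hat - e$d_bar / e$n_star)
  kn <- -kd * e$d_bar / e$n_star
  kb <- 1 - kd - kn * e$d_hat
  structure(list(kd = kd, kn = kn, kb = kb), class = "trial_weights")
}

#' Construct weights directly
#'
#' Mostly useful in tests and sensitivity analyses; ordinary use goes through
#' [derive_weights()].
#'
#' @param kd,kn,kb Numeric scalars; `kn` must be `<= 0`.
#' @return A `trial_weights` object.
#' @export
trial_weights <- function(kd, kn, kb) {
  stopifnot(is.numeric(kd), is.numeric(kn), is.numeric(kb))
  if (kn > 0) stop("kn must be non-positive (sampling is a cost)")
  structure(list(kd = kd, kn = kn, kb = kb), class = "trial_weights")
}

#' Utility parameters: weights plus attitude to risk
#'
#' The risk-attitude parameter `rho` turns value into utility through the
#' constant-absolute-risk-aversion (exponential) transform: `rho > 0` is
#' risk-averse, `rho = 0` risk-neutral (utility equals value), `rho < 0`
#' risk-seeking. Units of `rho` are inverse value units.
#'
#' @param weights A `trial_weights` object.
#' @param rho Numeric scalar.
#' @return An object of class `utility_params`.
#' @export
utility_params <- function(weights, rho) {
  stopifnot(inherits(weights, "trial_weights"),
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  structure(list(weights = weights, rho = rho), class = "utility_params")
}

#' Value of a realised programme outcome
#'
#' @param n Total participants across both arms and stages, as counted by the
#'   value function (sum of per-arm stage sizes).
#' @param d Realised change in mean outcome: the true effect if the
#'   intervention is adopted, 0 otherwise.
#' @param b Indicator, 1 if the control treatment is retained, 0 if the
#'   intervention is adopted. `d` must be 0 whenever `b = 1`.
#' @param w A `trial_weights` object.
#' @return `kn*n + kd*d + kb*b`. Vectorised over `n`, `d`, `b`.
#' @export
attribute_value <- function(n, d, b, w) {
  stopifnot(inherits(w, "trial_weights"), all(b %in% c(0, 1)))
  if (any(b == 1 & d != 0))
    stop("d must be 0 when the control is retained (b = 1)")
  w$kn * n + w$kd * d + w$kb * b
}

#' Exponential (CARA) value-to-utility transform
#'
#' `rho > 0`: `1 - exp(-rho*v)`; `rho = 0`: `v`; `rho < 0`:
#' `-1 + exp(-rho*v)`. Strictly increasing in `v` for every `rho`, and maps
#' `v = 0` to utility 0. The raw utilities scale with `rho` near 0 (utility
#' is only defined up to a positive affine transformation); the normalised
#' form `u / |rho|` tends to the linear `rho = 0` branch, so the preference
#' ordering is continuous in the risk attitude.
#'
#' @param v Numeric vector of values.
#' @param rho Risk-attitude scalar.
#' @return Utilities, same length as `v`.
#' @export
value_to_utility <- function(v, rho) {
  if (rho > 0) 1 - exp(-rho * v)
  else if (rho < 0) -1 + exp(-rho * v)
  else v
}

#' Inverse of the value-to-utility transform
#'
#' For `rho > 0` this is `-(1/rho) * log(1 - u)`, defined for `u < 1`; for
#' `rho < 0` it is `-(1/rho) * log(1 + u)`, defined for `u > -1`; for
#' `rho = 0` the identity.
#'
#' @param u Numeric vector of utilities.
#' @param rho Risk-attitude scalar.
#' @return Values, same length as `u`.
#' @export
utility_to_value <- function(u, rho) {
  if (rho > 0) {
    if (any(u >= 1)) stop("utility must be < 1 when rho > 0")
    -log(1 - u) / rho
  } else if (rho < 0) {
    if (any(u <= -1)) stop("utility must be > -1 when rho < 0")
    -log(1 + u) / rho
  } else u
}

#' Utility of a realised programme outcome
#'
#' @inheritParams attribute_value
#' @param p A `utility_params` object.
#' @return Utility of the outcome under `p`.
#' @export
attribute_utility <- function(n, d, b, p) {
  stopifnot(inherits(p, "utility_params"))
  value_to_utility(attribute_value(n, d, b, p$weights), p$rho)
}

# CE of a 50/50 gamble between d_min and d_max under exponential utility,
# taken over the d attribute directly (value = d, before weighting).
gamble_ce <- function(rho, d_min, d_max) {
  if (rho == 0) return((d_min + d_max) / 2)
  utility_to_value(0.5 * (value_to_utility(d_min, rho) +
                          value_to_utility(d_max, rho)), rho)
}

#' Risk attitude from a certainty equivalent
#'
#' Recovers `rho` from the certainty equivalent of a 50/50 gamble between two
#' outcomes `d_min` and `d_max` on the change-in-outcome attribute (the
#' gamble is over `d` directly, with `n = 0`, `b = 0`, so value equals `d`
#' before weighting). Solves
#' `u(ce) = (u(d_min) + u(d_max)) / 2` for `rho`, where `u` is the
#' exponential transform; a certainty equivalent at the midpoint gives
#' `rho = 0`, below it `rho > 0` (risk-averse), above it `rho < 0`.
#'
#' @param d_min,d_max Gamble outcomes, `d_min < d_max`, effect units.
#' @param certainty_equivalent The sure outcome judged equivalent to the
#'   gamble; must lie strictly between `d_min` and `d_max`.
#' @param tol Absolute tolerance on the root, default `1e-10`.
#' @return The risk-attitude scalar `rho`.
#' @export
#' @examples
#' rho_from_gamble(0, 0.5, 0.19)  # approximately 2
rho_from_gamble <- function(d_min, d_max, certainty_equivalent, tol = 1e-10) {
  stopifnot(d_min < d_max)
  ce <- certainty_equivalent
  if (ce <= d_min || ce >= d_max)
    stop("no finite solution: certainty equivalent must lie strictly ",
         "between d_min and d_max")
  mid <- (d_min + d_max) / 2
  if (ce == mid) return(0)
  # f is continuous and strictly decreasing in rho; bracket then expand
  f <- function(rho) gamble_ce(rho, d_min, d_max) - ce
  lo <- -50; hi <- 50
  while (f(lo) < 0) lo <- lo * 2
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Utility difference in participant-equivalent units
#'
#' Translates a gap between two (expected) utilities into participants by
#' mapping each utility back to the value scale and dividing the value
#' difference by the per-participant weight `|kn|`:
#' \deqn{\frac{1}{\rho |k_n|}\left[\log(1-u_{alt}) - \log(1-u_{best})\right]}
#' (for `rho > 0`; the matching branches are used for `rho <= 0`). This is
#' the regret currency used throughout the sensitivity analyses.
#'
#' @param u_best,u_alt Utilities with `u_best >= u_alt`, both in the domain
#'   of the inverse transform.
#' @param p A `utility_params` object.
#' @return Non-negative number of participants.
#' @export
regret_in_participants <- function(u_best, u_alt, p) {
  stopifnot(inherits(p, "utility_params"))
  if (u_best < u_alt) stop("u_best must be >= u_alt")
  if (p$weights$kn == 0)
    stop("kn is zero: participant units are undefined")
  (utility_to_value(u_best, p$rho) - utility_to_value(u_alt, p$rho)) /
    abs(p$weights$kn)
}

#' @export
print.trial_weights <- function(x, ...) {
  cat("Value-function weights:\n")
  cat(sprintf("  kd = %.6g (per effect unit)\n", x$kd))
  cat(sprintf("  kn = %.6g (per participant)\n", x$kn))
  cat(sprintf("  kb = %.6g (control retention)\n", x$kb))
  invisible(x)
}

#' @export
print.utility_params <- function(x, ...) {
  print(x$weights)
  att <- if (x$rho > 0) "risk-averse" else if (x$rho < 0) "risk-seeking"
         else "risk-neutral"
  cat(sprintf("Risk attitude: rho = %g (%s)\n", x$rho, att))
  invisible(x)
}
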