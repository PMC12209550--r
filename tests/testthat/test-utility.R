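test_that("weight derivation satisfies the defining identities", {
  cases <- list(
    list(e = elicitation(0.005, 0.3, 50),
         kd = 0.769, kn = -0.0000769, kb = 0.231, tol = 1e-3),
    # independently evaluated closed forms at a halved sampling cost
    list(e = elicitation(0.0025, 0.3, 50),
         kd = 0.769260356168, kn = -3.84630178084e-05,
         kb = 0.230751182738, tol = 1e-10))
  for (cs in cases) {
    w <- derive_weights(cs$e)
    # printed-precision agreement: within half the last printed digit
    expect_lt(abs(w$kd - cs$kd), cs$tol)
    expect_lt(abs(w$kn - cs$kn), cs$tol * abs(cs$kn) / cs$kd)
    expect_lt(abs(w$kb - cs$kb), cs$tol)
    # identities hold exactly for any valid inputs
    expect_equal(w$kd, 1 / (1 + cs$e$d_hat - cs$e$d_bar / cs$e$n_star))
    expect_equal(w$kn, -w$kd * cs$e$d_bar / cs$e$n_star)
    expect_equal(w$kb, 1 - w$kd - w$kn * cs$e$d_hat)
    expect_lt(w$kn, 0)
  }
  # zero-sampling-cost limit: kn -> 0, kd -> 1/1.3
  w0 <- derive_weights(elicitation(1e-12, 0.3, 50))
  expect_equal(w0$kd, 1 / 1.3, tolerance = 1e-12)
  expect_equal(w0$kn, 0, tolerance = 1e-12)
  expect_error(elicitation(-0.1, 0.3, 50), "d_bar")
  expect_error(elicitation(0.005, 0.3, 0), "n_star")
})

test_that("value function is the stated weighted sum of attributes", {
  w <- ok_weights()
  expect_lt(abs(attribute_value(0, 0, 1, w) - 0.231), 5e-4)
  expect_equal(attribute_value(0, 0, 0, w), 0)
  # hand evaluation of the printed value function
  expect_equal(attribute_value(100, 0.5, 0, trial_weights(0.769, -0.0000769,
                                                          0.231)),
               0.37681)
  expect_error(attribute_value(10, 0.3, 1, w), "b = 1")
})

test_that("utility transform branches agree and invert", {
  w <- ok_weights()
  # risk-neutral: utility equals value
  a <- list(n = 100, d = 0.4, b = 0)
  p0 <- utility_params(w, 0)
  expect_identical(attribute_utility(a$n, a$d, a$b, p0),
                   attribute_value(a$n, a$d, a$b, w))
  expect_equal(value_to_utility(0, 2), 0)
  # published pairing: an expected utility of 0.42874 is a value of 0.2800
  expect_lt(abs(utility_to_value(0.42874, 2) - 0.2800), 5e-5)
  # strictly increasing in value for each rho sign
  v <- seq(-2, 2, length.out = 101)
  for (rho in c(-2, 0, 2))
    expect_true(all(diff(value_to_utility(v, rho)) > 0))
  # the preference ordering is continuous at rho = 0: the affine-normalised
  # transform u/|rho| tends to the linear branch
  for (eps in c(1e-8, -1e-8))
    expect_equal(value_to_utility(v, eps) / abs(eps), v, tolerance = 1e-6)
  # round trip identity over random (value, rho) pairs on the attribute
  # scale (|v| <= 1: the weights sum to one)
  set.seed(42)
  for (i in 1:1000) {
    rho <- runif(1, -5, 5)
    vv <- runif(1, -1, 1)
    expect_equal(utility_to_value(value_to_utility(vv, rho), rho), vv,
                 tolerance = 1e-12)
  }
  expect_error(utility_to_value(1.2, 2), "< 1")
})

test_that("risk attitude is recovered from a certainty equivalent", {
  # midpoint <=> risk-neutral
  expect_identical(rho_from_gamble(0, 0.5, 0.25), 0)
  # worked example: CE 0.19 on a (0, 0.5) gamble ~ rho = 2 (CE is rounded)
  expect_equal(rho_from_gamble(0, 0.5, 0.19), 2, tolerance = 2e-3)
  # forward CE at rho = -2 is log((e+1)/2)/2; inversion recovers rho
  expect_equal(rho_from_gamble(0, 0.5, 0.310057253479), -2,
               tolerance = 1e-6)
  # exact inverse of the forward computation across the explored range
  for (rho in seq(-5, 5, by = 0.5)) {
    ce <- pilotopt:::gamble_ce(rho, -0.1, 0.6)
    expect_equal(rho_from_gamble(-0.1, 0.6, ce), rho, tolerance = 1e-6)
  }
  expect_error(rho_from_gamble(0, 0.5, 0.6), "between")
})

test_that("utility gaps translate to participant units", {
  p <- utility_params(ok_weights(), 2)
  expect_identical(regret_in_participants(0.3, 0.3, p), 0)
  # printed worked-example gap: values 0.2800 vs 0.2749 -> ~66 participants
  expect_equal(regret_in_participants(0.42874, 0.42292, p), 66,
               tolerance = 0.01)
  # value difference 0.0051 at |kn| = 0.0000769
  expect_equal(0.0051 / 0.0000769, 66.3, tolerance = 1e-3)
  # matches the brute-force two-step translation for rho != 0
  set.seed(7)
  for (i in 1:50) {
    rho <- runif(1, -4, 4); if (abs(rho) < 0.1) next
    pp <- utility_params(ok_weights(), rho)
    v1 <- runif(1, -0.5, 0.5); v2 <- v1 - runif(1, 0, 0.3)
    u1 <- value_to_utility(v1, rho); u2 <- value_to_utility(v2, rho)
    expect_equal(regret_in_participants(u1, u2, pp),
                 (v1 - v2) / abs(pp$weights$kn), tolerance = 1e-9)
  }
  # a common shift of both utilities leaves regret unchanged only at
  # rho = 0, where utility and value coincide
  p0 <- utility_params(ok_weights(), 0)
  expect_equal(regret_in_participants(0.3 + 0.1, 0.2 + 0.1, p0),
               regret_in_participants(0.3, 0.2, p0))
  expect_false(isTRUE(all.equal(
    regret_in_participants(0.3 + 0.1, 0.2 + 0.1, p),
    regret_in_participants(0.3, 0.2, p))))
  expect_error(regret_in_participants(0.1, 0.2, p), "u_best")
})
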