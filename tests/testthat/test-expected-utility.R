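test_that("branch probabilities sum to one and factor through stage 1", {
  sc <- ok_scenario()
  d <- design_from_alpha(41, 0.39, 146, 0.041, sc$sigma)
  mu <- seq(-1.5, 1.5, by = 0.25)
  p <- branch_probabilities(d, mu, sc)
  expect_equal(p$p11 + p$p10 + p$p0, rep(1, length(mu)), tolerance = 1e-12)
  p1 <- stage_power(d$n1, d$c1, mu, sc$sigma)
  p2 <- stage_power(d$n2, d$c2, mu, sc$sigma)
  expect_equal(p$p11, p1 * p2, tolerance = 1e-12)
  # c1 = -Inf: the pilot can never stop the programme
  d_open <- design_from_alpha(41, 1, 146, 0.041, sc$sigma)
  expect_equal(branch_probabilities(d_open, mu, sc)$p0, rep(0, length(mu)))
  # mu = c1 = c2 with equal stage SEs: (1/4, 1/4, 1/2) by symmetry
  d_sym <- programme_design(50, 0.2, 50, 0.2)
  p_sym <- branch_probabilities(d_sym, 0.2, sc)
  expect_equal(unname(unlist(p_sym)), c(0.25, 0.25, 0.5), tolerance = 1e-12)
})

test_that("conditional expected utility matches Monte Carlo", {
  sc <- ok_scenario()
  d <- design_from_alpha(41, 0.39, 146, 0.041, sc$sigma)
  for (mu in c(0, 0.5)) {
    sim <- simulate_programme(d, sc, n_sims = 4e5, seed = 101,
                              fixed_mu = mu)
    expect_lt(abs(conditional_eu(d, mu, sc) - sim$mean_utility),
              3 * sim$se)
  }
  # degenerate: no sampling and no tests means certain adoption
  d0 <- programme_design(0, -Inf, 0, -Inf)
  rho <- sc$utility$rho; kd <- sc$utility$weights$kd
  expect_equal(conditional_eu(d0, 0.4, sc), 1 - exp(-rho * kd * 0.4),
               tolerance = 1e-12)
  # no-pilot limit: reduces to the single definitive-trial expectation
  d_np <- design_from_alpha(0, 1, 146, 0.041, sc$sigma)
  p2 <- stage_power(146, d_np$c2, 0.3, sc$sigma)
  w <- sc$utility$weights
  expect_equal(conditional_eu(d_np, 0.3, sc),
               p2 * value_to_utility(w$kd * 0.3 + w$kn * 146, rho) +
                 (1 - p2) * value_to_utility(w$kn * 146 + w$kb, rho),
               tolerance = 1e-12)
})

test_that("prior expected utility agrees with a brute-force integration", {
  sc <- ok_scenario()
  # the third design has tight stage SEs (~0.12), which needs a denser
  # rule; pair each design with a node count passing the doubling check
  designs <- list(
    list(d = design_from_alpha(41, 0.39, 146, 0.041, sc$sigma), nodes = 151L),
    list(d = design_from_alpha(30, 0.8, 60, 0.2, sc$sigma), nodes = 151L),
    list(d = design_from_alpha(100, 0.05, 300, 0.01, sc$sigma),
         nodes = 301L))
  simpson <- function(f, mus) {
    h <- mus[2] - mus[1]
    n <- length(f)
    h / 3 * (f[1] + f[n] + 4 * sum(f[seq(2, n - 1, by = 2)]) +
               2 * sum(f[seq(3, n - 2, by = 2)]))
  }
  for (cs in designs) {
    sci <- sc; sci$nodes <- cs$nodes
    eu <- expected_utility(cs$d, sci)
    # composite-Simpson oracle over m +/- 10s
    mus <- seq(sc$prior$m - 10 * sc$prior$s, sc$prior$m + 10 * sc$prior$s,
               length.out = 200001)
    f <- conditional_eu(cs$d, mus, sci) * dnorm(mus, sc$prior$m, sc$prior$s)
    expect_lt(abs(eu - simpson(f, mus)), 1e-8)
  }
  # worked-example magnitude at the published unrestricted design
  d1 <- designs[[1]]$d
  expect_equal(abs(expected_utility(d1, sc)), 0.42874,
               tolerance = 2e-3 / 0.42874)
  # point-mass prior collapses to the conditional value
  sc0 <- ok_scenario(prior = effect_prior(0.3, 0))
  expect_identical(expected_utility(d1, sc0),
                   conditional_eu(d1, 0.3, sc0))
})

test_that("expected utility is representation- and parameter-stable", {
  sc <- ok_scenario()
  # (alpha1, alpha2) and (c1, c2) views give the same EU
  d <- design_from_alpha(41, 0.39, 146, 0.041, sc$sigma)
  d2 <- programme_design(41, d$c1, 146, d$c2)
  expect_identical(expected_utility(d, sc), expected_utility(d2, sc))
  # EU strictly decreases as the per-participant cost grows
  eus <- sapply(c(1, 2, 4), function(f) {
    w <- ok_weights(); w$kn <- w$kn * f
    sc2 <- sc; sc2$utility <- utility_params(w, 2)
    expected_utility(d, sc2)
  })
  expect_true(all(diff(eus) < 0))
  # the printed-form utilities scale with rho near 0; on the affine-
  # normalised scale u/|rho| the +/- eps expectations bracket the
  # risk-neutral EU (Jensen) and both tend to it
  eu0 <- expected_utility(d, ok_scenario(rho = 0))
  eup <- expected_utility(d, ok_scenario(rho = 1e-4)) / 1e-4
  eum <- expected_utility(d, ok_scenario(rho = -1e-4)) / 1e-4
  expect_lte(eup, eu0)
  expect_gte(eum, eu0)
  expect_equal(eup, eu0, tolerance = 1e-3)
  expect_equal(eum, eu0, tolerance = 1e-3)
  # doubling the node count does not move the result
  conv <- eu_convergence(d, sc)
  expect_lt(abs(conv$delta), 1e-8)
})

test_that("prior expected utility matches full programme simulation", {
  sc <- ok_scenario()
  set.seed(33)
  designs <- random_designs(10, seed = 33, sigma = sc$sigma)
  for (i in seq_along(designs)) {
    prior <- list(effect_prior(0, 0.6), effect_prior(0.2, 0.3),
                  effect_prior(-0.2, 0.8))[[1 + (i %% 3)]]
    sci <- ok_scenario(prior = prior)
    sim <- simulate_programme(designs[[i]], sci, n_sims = 2e5,
                              seed = 1000 + i)
    expect_lt(abs(expected_utility(designs[[i]], sci) - sim$mean_utility),
              3 * sim$se)
  }
})
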