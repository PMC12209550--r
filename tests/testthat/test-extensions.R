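test_that("pilot and pooled means have the stated joint distribution", {
  j <- internal_joint(45, 121, 1.5, 0.3)
  expect_equal(j$mean, c(0.3, 0.3))
  expect_equal(j$cov[1, 1], 2 * 1.5^2 / 45)
  expect_equal(j$cov[2, 2], 2 * 1.5^2 / 166)
  expect_equal(j$cov[1, 2], j$cov[2, 2]) # cov(x1, xt) = var(xt)
  expect_equal(j$corr, sqrt(45 / 166))
  # n2 = 0: pooled mean is the pilot mean
  j0 <- internal_joint(45, 0, 1.5, 0)
  expect_equal(j0$corr, 1)
  expect_equal(j0$cov[1, 1], j0$cov[2, 2])
  expect_equal(internal_joint(50, 50, 1, 0)$corr, sqrt(0.5))
  expect_error(internal_joint(0, 50, 1.5, 0), "n1")
  # empirical covariance of simulated (x1, xt)
  set.seed(5)
  n <- 2e5
  x1 <- rnorm(n, 0.3, sqrt(j$cov[1, 1]))
  x2 <- rnorm(n, 0.3, 1.5 * sqrt(2 / 121))
  xt <- (45 * x1 + 121 * x2) / 166
  emp <- cov(cbind(x1, xt))
  se <- 3 * j$cov / sqrt(n / 2) # generous SE bound for covariance entries
  expect_true(all(abs(emp - j$cov) < se + 3e-4))
})

test_that("bivariate orthant probabilities match mvtnorm", {
  skip_if_not_installed("mvtnorm")
  set.seed(8)
  for (r in c(-0.9, -0.3, 0, 0.5, sqrt(0.5), 0.95, 0.999)) {
    h <- runif(40, -5, 5); k <- runif(40, -5, 5)
    S <- matrix(c(1, r, r, 1), 2)
    ref <- sapply(seq_along(h), function(i)
      mvtnorm::pmvnorm(lower = c(h[i], k[i]), upper = c(Inf, Inf),
                       sigma = S, algorithm = mvtnorm::TVPACK(1e-14))[1])
    expect_equal(pilotopt:::bvn_upper(h, k, r), ref, tolerance = 1e-10)
  }
  # infinite bounds
  expect_equal(pilotopt:::bvn_upper(-Inf, 0.3, 0.6),
               pnorm(0.3, lower.tail = FALSE))
  expect_equal(pilotopt:::bvn_upper(0.3, -Inf, 0.6),
               pnorm(0.3, lower.tail = FALSE))
  expect_equal(pilotopt:::bvn_upper(Inf, 0.3, 0.6), 0)
})

test_that("internal-pilot expected utility is coherent and simulable", {
  sc <- ok_scenario()
  # degenerate pooling (n2 = 0, c2 = c1) equals the external single-stage EU
  c1 <- critical_value(45, 0.3, sc$sigma)
  d_int <- programme_design(45, c1, 0, c1, pilot_type = "internal")
  d_ext <- programme_design(45, c1, 0, -Inf, pilot_type = "external")
  # with n2 = 0 the design constructor maps c2 to -Inf (always adopt on a
  # positive pilot); build the internal comparison directly instead
  d_int$c2 <- c1
  expect_equal(expected_utility(d_int, sc), expected_utility(d_ext, sc),
               tolerance = 1e-9)
  # published internal optimum magnitude
  d_t2 <- programme_design(45, critical_value(45, 0.42, sc$sigma), 121,
                           0.3455268, pilot_type = "internal")
  expect_equal(abs(expected_utility(d_t2, sc)), 0.42954,
               tolerance = 2e-3 / 0.42954)
  # Monte Carlo agreement for random internal designs
  designs <- random_designs(5, seed = 77, sigma = sc$sigma,
                            pilot_type = "internal")
  for (i in seq_along(designs)) {
    sim <- simulate_programme(designs[[i]], sc, n_sims = 2e5,
                              seed = 2000 + i)
    expect_lt(abs(expected_utility(designs[[i]], sc) - sim$mean_utility),
              3 * sim$se)
  }
})

test_that("conditional pilot sampling distribution is correct", {
  pr <- bivariate_effect_prior(0, 0.6, 0, 0.6, 0.9)
  cond <- pilot_sampling_given_mu(pr, 0.5, 30, 1.5)
  expect_equal(cond$mean, 0.9 * 0.5)
  expect_equal(cond$sd, sqrt((1 - 0.81) * 0.36 + 2 * 2.25 / 30))
  # prior-only part: residual SD of the pilot effect given mu is ~0.26
  expect_equal(sqrt(1 - 0.9^2) * 0.6, 0.26, tolerance = 6e-3)
  # homogeneous recovery at tau = 1
  pr1 <- bivariate_effect_prior(0, 0.6, 0, 0.6, 1)
  cond1 <- pilot_sampling_given_mu(pr1, 0.5, 30, 1.5)
  expect_equal(cond1$mean, 0.5)
  expect_equal(cond1$sd, 1.5 * sqrt(2 / 30))
  expect_error(pilot_sampling_given_mu(
    bivariate_effect_prior(0, 0.6, 0, 0, 0.5), 0.5, 30, 1.5), "undefined")
  # empirical check of the marginalised pilot sampling law
  set.seed(12)
  n <- 2e5
  mup <- rnorm(n, 0.9 * 0.5, sqrt(1 - 0.81) * 0.6)
  x1 <- rnorm(n, mup, 1.5 * sqrt(2 / 30))
  expect_lt(abs(mean(x1) - cond$mean), 3 * cond$sd / sqrt(n))
  expect_lt(abs(sd(x1) - cond$sd), 3 * cond$sd / sqrt(2 * n))
})

test_that("heterogeneous-effect expected utility nests the homogeneous", {
  sc <- ok_scenario()
  designs <- random_designs(10, seed = 55, sigma = sc$sigma)
  sc_t1 <- ok_scenario(prior = bivariate_effect_prior(0, 0.6, 0, 0.6, 1))
  for (d in designs)
    expect_equal(expected_utility(d, sc_t1), expected_utility(d, sc),
                 tolerance = 1e-10)
  # published tau = 0.9 optimum magnitude
  sc_t9 <- ok_scenario(prior = bivariate_effect_prior(0, 0.6, 0, 0.6, 0.9))
  d_t3 <- design_from_alpha(30, 0.69, 134, 0.034, sc$sigma)
  expect_equal(abs(expected_utility(d_t3, sc_t9)), 0.42656,
               tolerance = 2e-3 / 0.42656)
  # EU increases with tau at the tau = 1 optimal design
  d_opt <- design_from_alpha(41, 0.39, 146, 0.041, sc$sigma)
  eus <- sapply(seq(0.5, 1, by = 0.1), function(tv)
    expected_utility(d_opt,
                     ok_scenario(prior = bivariate_effect_prior(0, 0.6, 0,
                                                                0.6, tv))))
  expect_true(all(diff(eus) > 0))
  # Monte Carlo agreement under the joint (mu_p, mu) draw
  for (i in 1:5) {
    sim <- simulate_programme(designs[[i]], sc_t9, n_sims = 2e5,
                              seed = 3000 + i)
    expect_lt(abs(expected_utility(designs[[i]], sc_t9) - sim$mean_utility),
              3 * sim$se)
  }
})
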