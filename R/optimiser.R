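#' Constraints on the programme design space
#'
#' @param n1_min,n1_max Bounds on the per-arm pilot size.
#' @param n2_min,n2_max Bounds on the per-arm definitive-stage size.
#' @param no_pilot_test If `TRUE`, the pilot collects data but is not
#'   tested: `alpha1 = 1` (`c1 = -Inf`, so `beta1 = 0`) and `n1` is fixed at
#'   `n1_min` (the size needed for the pilot's feasibility objectives).
#' @param pilot_type `"external"` or `"internal"`.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(n1_min = 0L, n1_max = 2000L,
                               n2_min = 0L, n2_max = 2000L,
                               no_pilot_test = FALSE,
                               pilot_type = "external") {
  pilot_type <- match.arg(pilot_type, c("external", "internal"))
  stopifnot(n1_min >= 0, n1_min <= n1_max, n2_min >= 0, n2_min <= n2_max)
  if (pilot_type == "internal" && n1_min < 1)
    n1_min <- 1L
  structure(list(n1_min = as.integer(n1_min), n1_max = as.integer(n1_max),
                 n2_min = as.integer(n2_min), n2_max = as.integer(n2_max),
                 no_pilot_test = isTRUE(no_pilot_test),
                 pilot_type = pilot_type),
            class = "design_constraints")
}

# Build a programme_design from the optimiser's transformed coordinates.
# Continuous n's are allowed here (the EU functions accept them); integer
# designs are produced by the refinement step.
design_from_par <- function(n1, n2, la1, la2, sigma, pilot_type) {
  a1 <- stats::plogis(la1); a2 <- stats::plogis(la2)
  c1 <- if (n1 == 0) -Inf else sigma * sqrt(2 / n1) * stats::qnorm(1 - a1)
  nt <- if (pilot_type == "internal") n1 + n2 else n2
  c2 <- if (nt == 0) -Inf else sigma * sqrt(2 / nt) * stats::qnorm(1 - a2)
  structure(list(n1 = n1, c1 = c1, n2 = n2, c2 = c2,
                 pilot_type = pilot_type),
            class = "programme_design")
}

# EU as a function of (possibly fractional) design coordinates.
eu_at <- function(n1, n2, la1, la2, scenario, pilot_type) {
  d <- design_from_par(n1, n2, la1, la2, scenario$sigma, pilot_type)
  if (pilot_type == "internal")
    expected_utility_internal(d, scenario)
  else if (inherits(scenario$prior, "bivariate_effect_prior"))
    expected_utility_heterogeneous(d, scenario)
  else prior_integral(function(mu) conditional_eu(d, mu, scenario),
                      scenario$prior$m, scenario$prior$s, scenario$nodes)
}

# Optimise the critical values only, for fixed integer (n1, n2). Stage
# alphas are profiled on the logit scale. Fixed stages are signalled by
# fix_la1/fix_la2 (e.g. la1 = Inf encodes alpha1 = 1).
optimise_cs <- function(n1, n2, scenario, pilot_type,
                        start = c(0, -2), fix_la1 = NULL, fix_la2 = NULL) {
  free1 <- is.null(fix_la1) && n1 > 0
  free2 <- is.null(fix_la2) && n2 > 0
  la1 <- if (free1) start[1] else if (n1 == 0) Inf else fix_la1
  la2 <- if (free2) start[2] else if (n2 == 0) Inf else fix_la2
  obj <- function(p) {
    i <- 1
    if (free1) { la1 <- p[i]; i <- i + 1 }
    if (free2) la2 <- p[i]
    -eu_at(n1, n2, la1, la2, scenario, pilot_type)
  }
  p0 <- c(if (free1) start[1], if (free2) start[2])
  if (length(p0) == 0)
    return(list(la1 = la1, la2 = la2, eu = -obj(numeric(0)),
                convergence = 0L))
  fit <- stats::optim(p0, obj, method = "L-BFGS-B",
                      lower = rep(-13, length(p0)),
                      upper = rep(13, length(p0)),
                      control = list(factr = 1e4))
  i <- 1
  if (free1) { la1 <- fit$par[i]; i <- i + 1 }
  if (free2) la2 <- fit$par[i]
  list(la1 = la1, la2 = la2, eu = -fit$value, convergence = fit$convergence)
}

# L-BFGS-B wrapper that drops coordinates whose box has zero width (it
# cannot finite-difference those), returning the full parameter vector.
optim_boxed <- function(p0, f, lower, upper) {
  fixed <- upper - lower < 1e-12
  if (all(fixed))
    return(list(par = lower, value = f(lower), convergence = 0L))
  g <- function(q) {
    p <- lower
    p[!fixed] <- q
    f(p)
  }
  fit <- stats::optim(pmin(pmax(p0[!fixed], lower[!fixed]), upper[!fixed]),
                      g, method = "L-BFGS-B", lower = lower[!fixed],
                      upper = upper[!fixed], control = list(factr = 1e4))
  par <- lower
  par[!fixed] <- fit$par
  list(par = par, value = fit$value, convergence = fit$convergence)
}

# Multi-start continuous relaxation over (log n1, log n2, logit a1,
# logit a2), followed by exhaustive refinement over the +/-2 integer
# neighbourhood with the critical values re-optimised for each candidate.
optimise_interior <- function(scenario, cons, extra_starts = NULL,
                              n_refine = 2L) {
  pt <- cons$pilot_type
  n1_lo <- max(cons$n1_min, 1L); n2_lo <- max(cons$n2_min, 1L)
  obj <- function(p) -eu_at(exp(p[1]), exp(p[2]), p[3], p[4], scenario, pt)
  n_conv <- solve_sample_size(0.9, 0.025, max(abs(scenario$mu_star), 1e-3),
                              scenario$sigma)
  n_pairs <- list(c(max(n1_lo, 15L), min(n_conv, cons$n2_max)),
                  c(max(n1_lo, 40L), min(max(round(n_conv / 2), n2_lo),
                                         cons$n2_max)))
  alphas <- c(0.05, 0.3, 0.7, 0.95)
  starts <- list()
  for (np in n_pairs) for (a1 in alphas) for (a2 in alphas)
    starts[[length(starts) + 1L]] <-
      c(log(np[1]), log(np[2]), stats::qlogis(a1), stats::qlogis(a2))
  for (es in extra_starts) starts[[length(starts) + 1L]] <- es
  lower <- c(log(n1_lo), log(n2_lo), -13, -13)
  upper <- c(log(cons$n1_max), log(cons$n2_max), 13, 13)
  best <- NULL; n_ok <- 0L
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(optim_boxed(p0, obj, lower, upper),
                    error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimisation failure: no start point converged (",
         length(starts), " starts attempted)")
  n1c <- exp(best$par[1]); n2c <- exp(best$par[2])
  cand <- expand.grid(
    n1 = unique(pmin(pmax(round(n1c) + (-n_refine):n_refine, n1_lo),
                     cons$n1_max)),
    n2 = unique(pmin(pmax(round(n2c) + (-n_refine):n_refine, n2_lo),
                     cons$n2_max)))
  sols <- lapply(seq_len(nrow(cand)), function(i)
    c(as.list(cand[i, ]),
      optimise_cs(cand$n1[i], cand$n2[i], scenario, pt,
                  start = best$par[3:4])))
  pick_best(sols, starts_tried = length(starts), starts_ok = n_ok)
}

# Tie rule: EU within 1e-10 prefers smaller n1+n2, then smaller n1.
pick_best <- function(sols, starts_tried = NA_integer_,
                      starts_ok = NA_integer_) {
  eus <- vapply(sols, `[[`, numeric(1), "eu")
  keep <- which(eus >= max(eus) - 1e-10)
  tot <- vapply(sols[keep], function(s) s$n1 + s$n2, numeric(1))
  keep <- keep[tot == min(tot)]
  n1s <- vapply(sols[keep], `[[`, numeric(1), "n1")
  s <- sols[[keep[which.min(n1s)]]]
  s$starts_tried <- starts_tried; s$starts_ok <- starts_ok
  s
}

#' Maximise expected utility over the programme design
#'
#' Finds the programme design `(n1, c1, n2, c2)` maximising prior expected
#' utility, subject to box constraints on the per-arm sample sizes and
#' optionally to the "no pilot test" restriction. The sample sizes are first
#' relaxed to continuous values and optimised on a log scale (with stage
#' alphas on a logit scale) by multi-start box-constrained quasi-Newton
#' (`optim(method = "L-BFGS-B")`, 32 deterministic starts); the integer
#' neighbourhood (+/-2 per stage) of the continuous solution is then
#' searched exhaustively, re-optimising the critical values for each
#' candidate. Degenerate boundary designs -- no definitive stage
#' (`n2 = 0`), no pilot (`n1 = 0`, when allowed), or no trial at all -- are
#' evaluated as separate candidates, since the log-scale relaxation cannot
#' reach them. Ties in expected utility (within 1e-10) are broken towards
#' smaller `n1 + n2`, then smaller `n1`. The whole procedure is
#' deterministic.
#'
#' @param scenario A `trial_scenario`. A `bivariate_effect_prior` in the
#'   scenario selects the heterogeneous-effect objective.
#' @param constraints A [design_constraints()] object; its `pilot_type`
#'   selects the external or internal objective.
#' @param extra_starts Optional list of additional start points on the
#'   transformed scale `c(log n1, log n2, qlogis a1, qlogis a2)` (used by
#'   the sweep functions for warm starting).
#' @return An object of class `optimal_programme`: list with `design`
#'   (a `programme_design`), `expected_utility`, `oc` (the
#'   [operating_characteristics()] at the scenario's `mu_star`), and
#'   `diagnostics` (start counts).
#' @export
#' @examples
#' \donttest{
#' sc <- ok_diabetes_scenario()
#' optimise_programme(sc, design_constraints(n1_min = 30))
#' }
optimise_programme <- function(scenario, constraints = design_constraints(),
                               extra_starts = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"),
            inherits(constraints, "design_constraints"))
  cons <- constraints; pt <- cons$pilot_type
  if (pt == "internal" && inherits(scenario$prior, "bivariate_effect_prior"))
    stop("internal pilots with a bivariate effect prior are not supported")
  sols <- list()
  if (cons$no_pilot_test) {
    # pilot runs (n1 = n1_min) but is not tested: alpha1 = 1, c1 = -Inf
    n1 <- cons$n1_min
    if (pt == "internal")
      stop("no_pilot_test with an internal pilot is not supported")
    sols[[length(sols) + 1L]] <- optimise_interior_n1fixed(scenario, cons, n1)
    if (cons$n2_min == 0)
      sols[[length(sols) + 1L]] <-
        list(n1 = n1, n2 = 0, la1 = Inf, la2 = Inf,
             eu = eu_at(n1, 0, Inf, Inf, scenario, pt), convergence = 0L)
  } else {
    sols[[length(sols) + 1L]] <- optimise_interior(scenario, cons,
                                                   extra_starts)
    # boundary: pilot only (n2 = 0, adopt on a positive pilot test)
    if (cons$n2_min == 0) {
      s <- optimise_single_stage(scenario, cons, stage = 1L)
      sols[[length(sols) + 1L]] <- s
    }
    # boundary: definitive only (n1 = 0; only meaningful for external)
    if (cons$n1_min == 0 && pt == "external") {
      s <- optimise_single_stage(scenario, cons, stage = 2L)
      sols[[length(sols) + 1L]] <- s
      if (cons$n2_min == 0)
        sols[[length(sols) + 1L]] <-
          list(n1 = 0, n2 = 0, la1 = Inf, la2 = Inf,
               eu = eu_at(0, 0, Inf, Inf, scenario, pt), convergence = 0L)
    }
  }
  s <- pick_best(sols,
                 starts_tried = sum(vapply(sols, function(x)
                   if (is.null(x$starts_tried)) 1L else x$starts_tried,
                   integer(1))),
                 starts_ok = NA_integer_)
  d <- design_from_par(s$n1, s$n2, s$la1, s$la2, scenario$sigma, pt)
  d$n1 <- as.integer(round(d$n1)); d$n2 <- as.integer(round(d$n2))
  structure(list(design = d,
                 expected_utility = s$eu,
                 oc = operating_characteristics(d, scenario),
                 diagnostics = list(starts = s$starts_tried,
                                    convergence = s$convergence)),
            class = "optimal_programme")
}

# no-pilot-test case: n1 fixed, alpha1 = 1; optimise (n2, c2) only.
optimise_interior_n1fixed <- function(scenario, cons, n1) {
  pt <- cons$pilot_type
  n2_lo <- max(cons$n2_min, 1L)
  obj <- function(p) -eu_at(n1, exp(p[1]), Inf, p[2], scenario, pt)
  n_conv <- solve_sample_size(0.9, 0.025, max(abs(scenario$mu_star), 1e-3),
                              scenario$sigma)
  starts <- list()
  for (n2s in unique(pmin(pmax(c(round(n_conv / 2), n_conv), n2_lo),
                          cons$n2_max)))
    for (a2 in c(0.05, 0.3, 0.7, 0.95))
      starts[[length(starts) + 1L]] <- c(log(n2s), stats::qlogis(a2))
  lower <- c(log(n2_lo), -13); upper <- c(log(cons$n2_max), 13)
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(optim_boxed(p0, obj, lower, upper),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("optimisation failure in the no-pilot-test case")
  n2c <- round(exp(best$par[1]))
  cand <- unique(pmin(pmax(n2c + (-2):2, n2_lo), cons$n2_max))
  sols <- lapply(cand, function(n2)
    c(list(n1 = n1, n2 = n2),
      optimise_cs(n1, n2, scenario, pt, start = c(0, best$par[2]),
                  fix_la1 = Inf)))
  pick_best(sols, starts_tried = length(starts))
}

# Single-stage boundary candidates: stage = 1 keeps only the pilot
# (n2 = 0, a positive pilot adopts); stage = 2 skips the pilot (n1 = 0).
optimise_single_stage <- function(scenario, cons, stage) {
  pt <- cons$pilot_type
  if (stage == 1L) {
    n_lo <- max(cons$n1_min, 1L); n_hi <- cons$n1_max
  } else {
    n_lo <- max(cons$n2_min, 1L); n_hi <- cons$n2_max
  }
  obj <- function(p) {
    if (stage == 1L) -eu_at(exp(p[1]), 0, p[2], Inf, scenario, pt)
    else -eu_at(0, exp(p[1]), Inf, p[2], scenario, pt)
  }
  n_conv <- solve_sample_size(0.9, 0.025, max(abs(scenario$mu_star), 1e-3),
                              scenario$sigma)
  starts <- list()
  for (ns in unique(pmin(pmax(c(30, n_conv), n_lo), n_hi)))
    for (a in c(0.05, 0.3, 0.7, 0.95))
      starts[[length(starts) + 1L]] <- c(log(ns), stats::qlogis(a))
  lower <- c(log(n_lo), -13); upper <- c(log(n_hi), 13)
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(optim_boxed(p0, obj, lower, upper),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("optimisation failure in a boundary candidate")
  nc <- round(exp(best$par[1]))
  cand <- unique(pmin(pmax(nc + (-2):2, n_lo), n_hi))
  sols <- lapply(cand, function(n) {
    if (stage == 1L)
      c(list(n1 = n, n2 = 0),
        optimise_cs(n, 0, scenario, pt, start = c(best$par[2], 0)))
    else
      c(list(n1 = 0, n2 = n),
        optimise_cs(0, n, scenario, pt, start = c(0, best$par[2]),
                    fix_la1 = Inf))
  })
  pick_best(sols, starts_tried = length(starts))
}

#' Optimal internal-pilot programme
#'
#' Convenience wrapper: [optimise_programme()] with
#' `pilot_type = "internal"` in the constraints.
#'
#' @inheritParams optimise_programme
#' @return An `optimal_programme`.
#' @export
optimise_internal <- function(scenario, constraints = design_constraints(
                                n1_min = 1, pilot_type = "internal")) {
  constraints$pilot_type <- "internal"
  if (constraints$n1_min < 1) constraints$n1_min <- 1L
  optimise_programme(scenario, constraints)
}

# transformed-scale start point corresponding to a fitted optimum
warm_start_par <- function(opt, scenario) {
  d <- opt$design
  a1 <- implied_alpha(max(d$n1, 1), d$c1, scenario$sigma)
  nt <- if (d$pilot_type == "internal") d$n1 + d$n2 else d$n2
  a2 <- implied_alpha(max(nt, 1), d$c2, scenario$sigma)
  clamp <- function(a) pmin(pmax(a, 1e-6), 1 - 1e-6)
  c(log(max(d$n1, 1)), log(max(d$n2, 1)),
    stats::qlogis(clamp(a1)), stats::qlogis(clamp(a2)))
}

# shared machinery for the parameter sweeps: re-optimise under a sequence
# of modified scenarios, warm-starting each solve from its neighbour.
sweep_over <- function(grid, scenario_at, constraints) {
  rows <- vector("list", length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    sc_i <- scenario_at(grid[i])
    opt <- tryCatch(
      optimise_programme(sc_i, constraints, extra_starts = warm),
      error = function(e) e)
    if (inherits(opt, "error")) {
      rows[[i]] <- data.frame(value = grid[i], n1 = NA, n2 = NA,
                              alpha1 = NA, beta1 = NA, alpha2 = NA,
                              beta2 = NA, alpha_t = NA, beta_t = NA,
                              eu = NA, failed = TRUE)
      next
    }
    warm <- list(warm_start_par(opt, sc_i))
    oc <- opt$oc
    rows[[i]] <- data.frame(value = grid[i],
                            n1 = opt$design$n1, n2 = opt$design$n2,
                            alpha1 = oc$alpha1, beta1 = oc$beta1,
                            alpha2 = oc$alpha2, beta2 = oc$beta2,
                            alpha_t = oc$alpha_t, beta_t = oc$beta_t,
                            eu = opt$expected_utility, failed = FALSE)
  }
  do.call(rbind, rows)
}

#' Optimal designs over a grid of risk attitudes
#'
#' Re-optimises the programme for each value of `rho`, holding every other
#' scenario parameter fixed, warm-starting each solve from its neighbour's
#' optimum. Supports trend analyses of how the optimal stage error rates
#' move with the attitude to risk.
#'
#' @param scenario Base `trial_scenario`; its `utility$rho` is replaced by
#'   each grid value in turn.
#' @param rho_grid Numeric vector of risk-attitude values.
#' @param constraints A [design_constraints()].
#' @return A data frame with one row per `rho` (column `rho`), the optimal
#'   design's sizes and error rates, its expected utility, and a `failed`
#'   flag for per-point optimiser failures.
#' @export
rho_sweep <- function(scenario, rho_grid, constraints = design_constraints()) {
  out <- sweep_over(rho_grid, function(r) {
    sc <- scenario
    sc$utility <- utility_params(scenario$utility$weights, r)
    sc
  }, constraints)
  names(out)[names(out) == "value"] <- "rho"
  out
}

#' Optimal designs over a grid of pilot/definitive effect correlations
#'
#' Re-optimises the (external) programme for each correlation `tau` of the
#' bivariate heterogeneous-effect prior, keeping the marginal priors fixed.
#'
#' @param scenario Base `trial_scenario` whose prior is a
#'   [bivariate_effect_prior()] (or a univariate prior, which is promoted
#'   to a bivariate prior with matching marginals).
#' @param tau_grid Numeric vector of correlations in `[-1, 1]`.
#' @param constraints A [design_constraints()].
#' @return A data frame as in [rho_sweep()], with column `tau`.
#' @export
tau_sweep <- function(scenario, tau_grid, constraints = design_constraints()) {
  pr <- scenario$prior
  if (!inherits(pr, "bivariate_effect_prior"))
    pr <- bivariate_effect_prior(pr$m, pr$s, pr$m, pr$s, 1)
  out <- sweep_over(tau_grid, function(tv) {
    sc <- scenario
    sc$prior <- bivariate_effect_prior(pr$mp, pr$sp, pr$m, pr$s, tv)
    sc
  }, constraints)
  names(out)[names(out) == "value"] <- "tau"
  out
}

#' @export
print.optimal_programme <- function(x, ...) {
  cat("Optimal trial programme\n")
  print(x$design)
  cat(sprintf("  expected utility: %.5f\n", x$expected_utility))
  print(x$oc)
  invisible(x)
}
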