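# Worked-example scenario built in code (the YAML fixture is exercised
# separately in test-config.R).
ok_weights <- function() derive_weights(elicitation(0.005, 0.3, 50))

ok_scenario <- function(rho = 2, nodes = 151L, prior = effect_prior(0, 0.6)) {
  scenario(sigma = 1.5, prior = prior,
           utility = utility_params(ok_weights(), rho),
           mu_star = 0.5, nodes = nodes)
}

ok_constraints <- function(...) design_constraints(n1_min = 30, ...)

# memoise expensive optimisations across test files (one R session per run)
.opt_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.opt_cache[[key]])) .opt_cache[[key]] <- force(expr)
  .opt_cache[[key]]
}

ok_unrestricted <- function()
  cached("unrestricted", optimise_programme(ok_scenario(), ok_constraints()))

ok_no_pilot_test <- function()
  cached("no_pilot_test",
         optimise_programme(ok_scenario(),
                            ok_constraints(no_pilot_test = TRUE)))

# deterministic pseudo-random feasible designs for dominance checks
random_designs <- function(n, seed, sigma, pilot_type = "external",
                           n1_min = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    n1 <- sample(n1_min:200, 1)
    n2 <- sample(if (pilot_type == "internal") 0:400 else 0:400, 1)
    design_from_alpha(n1, runif(1, 0.01, 0.99), n2, runif(1, 0.01, 0.99),
                      sigma, pilot_type = pilot_type)
  })
}
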