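# key-set validation: unknown keys are rejected with a named error
check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown config key", if (length(extra) > 1) "s", " in ", where,
         ": ", paste(extra, collapse = ", "))
  invisible(x)
}

need <- function(x, key, where) {
  if (is.null(x[[key]])) stop("missing config key in ", where, ": ", key)
  x[[key]]
}

#' Load a run configuration
#'
#' Reads a YAML configuration describing a scenario (endpoint SD, effect
#' prior, utility inputs, alternative effect), design constraints, and run
#' options, validates it (unknown keys are rejected, required keys named
#' when missing), and assembles the package objects. The risk attitude may
#' be given directly (`utility.rho`) or through a certainty-equivalent
#' gamble (`utility.gamble` with `d_min`, `d_max`, `ce`), in which case
#' [rho_from_gamble()] is applied.
#'
#' @param path Path to a YAML file; see the bundled example
#'   `system.file("extdata", "ok_diabetes.yaml", package = "pilotopt")`.
#' @return A list of class `run_config`: `scenario` (a `trial_scenario`),
#'   `constraints` (a [design_constraints()]), `elicitation` (the
#'   [elicitation()] behind the weights), and `options` (a list with
#'   `nodes`, `seed`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw)) stop("empty config file: ", path)
  check_keys(raw, c("scenario", "constraints", "options"), "top level")
  sc <- need(raw, "scenario", "top level")
  check_keys(sc, c("sigma", "mu_star", "prior", "utility"), "scenario")
  prior_raw <- need(sc, "prior", "scenario")
  check_keys(prior_raw, c("kind", "m", "s", "mp", "sp", "tau"),
             "scenario.prior")
  kind <- if (is.null(prior_raw$kind)) "univariate" else prior_raw$kind
  prior <- if (kind == "bivariate") {
    bivariate_effect_prior(need(prior_raw, "mp", "scenario.prior"),
                           need(prior_raw, "sp", "scenario.prior"),
                           need(prior_raw, "m", "scenario.prior"),
                           need(prior_raw, "s", "scenario.prior"),
                           need(prior_raw, "tau", "scenario.prior"))
  } else if (kind == "univariate") {
    effect_prior(need(prior_raw, "m", "scenario.prior"),
                 need(prior_raw, "s", "scenario.prior"))
  } else stop("scenario.prior.kind must be 'univariate' or 'bivariate'")
  ut <- need(sc, "utility", "scenario")
  check_keys(ut, c("d_bar", "d_hat", "n_star", "rho", "gamble"),
             "scenario.utility")
  elic <- elicitation(need(ut, "d_bar", "scenario.utility"),
                      need(ut, "d_hat", "scenario.utility"),
                      need(ut, "n_star", "scenario.utility"))
  rho <- if (!is.null(ut$rho)) {
    if (!is.null(ut$gamble))
      stop("give either scenario.utility.rho or scenario.utility.gamble, ",
           "not both")
    ut$rho
  } else {
    g <- need(ut, "gamble", "scenario.utility")
    check_keys(g, c("d_min", "d_max", "ce"), "scenario.utility.gamble")
    rho_from_gamble(need(g, "d_min", "gamble"), need(g, "d_max", "gamble"),
                    need(g, "ce", "gamble"))
  }
  cons_raw <- if (is.null(raw$constraints)) list() else raw$constraints
  check_keys(cons_raw, c("n1_min", "n1_max", "n2_min", "n2_max",
                         "no_pilot_test", "pilot_type"), "constraints")
  cons <- do.call(design_constraints, cons_raw)
  opt_raw <- if (is.null(raw$options)) list() else raw$options
  check_keys(opt_raw, c("nodes", "seed"), "options")
  nodes <- if (is.null(opt_raw$nodes)) 151L else opt_raw$nodes
  scen <- scenario(need(sc, "sigma", "scenario"), prior,
                   utility_params(derive_weights(elic), rho),
                   need(sc, "mu_star", "scenario"), nodes = nodes)
  structure(list(scenario = scen, constraints = cons, elicitation = elic,
                 options = list(nodes = nodes, seed = opt_raw$seed)),
            class = "run_config")
}

#' Serialise a run configuration back to the YAML schema
#'
#' Inverse of [load_config()] (up to the `rho`-vs-gamble choice, which is
#' always written as `rho`): useful for recording exactly which scenario a
#' set of results was produced under.
#'
#' @param config A `run_config`.
#' @param path Optional file path; if omitted the YAML text is returned.
#' @return The YAML text, invisibly when written to a file.
#' @export
write_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario; pr <- sc$prior
  prior <- if (inherits(pr, "bivariate_effect_prior"))
    list(kind = "bivariate", m = pr$m, s = pr$s, mp = pr$mp, sp = pr$sp,
         tau = pr$tau)
  else list(kind = "univariate", m = pr$m, s = pr$s)
  e <- config$elicitation
  out <- list(
    scenario = list(sigma = sc$sigma, mu_star = sc$mu_star, prior = prior,
                    utility = list(d_bar = e$d_bar, d_hat = e$d_hat,
                                   n_star = e$n_star,
                                   rho = sc$utility$rho)),
    constraints = list(n1_min = config$constraints$n1_min,
                       n1_max = config$constraints$n1_max,
                       n2_min = config$constraints$n2_min,
                       n2_max = config$constraints$n2_max,
                       no_pilot_test = config$constraints$no_pilot_test,
                       pilot_type = config$constraints$pilot_type),
    options = list(nodes = sc$nodes))
  if (!is.null(config$options$seed)) out$options$seed <- config$options$seed
  txt <- yaml::as.yaml(out)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' The OK-Diabetes worked-example scenario
#'
#' The re-design setting of the OK-Diabetes feasibility study (supported
#' self-management for adults with learning disabilities and type II
#' diabetes): HbA1c change endpoint with known SD 1.5 (% units), sceptical
#' effect prior N(0, 0.6^2), target difference `mu_star = 0.5`, elicited
#' utility inputs `d_bar = 0.005`, `d_hat = 0.3`, `n_star = 50`, and a
#' risk-averse attitude `rho = 2`. The mean *reduction* of 0.5% that
#' motivated the trial is mapped to a positive effect, larger-is-better
#' scale. Shipped as a YAML fixture in `inst/extdata/ok_diabetes.yaml`; this
#' helper loads it.
#'
#' @return A `trial_scenario`.
#' @export
#' @examples
#' ok_diabetes_scenario()
ok_diabetes_scenario <- function() {
  load_config(system.file("extdata", "ok_diabetes.yaml",
                          package = "pilotopt"))$scenario
}

#' Tabulate optimised programmes
#'
#' Collects one or more [optimise_programme()] results into a table with the
#' conventional reporting columns. Stage-level columns are always present;
#' the programme-level `alpha_t`, `beta_t` columns are the natural summary
#' for internal pilots, where stage-2 rates refer to the pooled test.
#'
#' @param results A named list of `optimal_programme` objects (names become
#'   the `problem` column), or a single one.
#' @return A data frame with columns `problem`, `pilot_type`, `n1`, `n2`,
#'   `alpha1`, `beta1`, `alpha2`, `beta2`, `alpha_t`, `beta_t`, `eu`.
#' @export
programme_table <- function(results) {
  if (inherits(results, "optimal_programme")) results <- list(results)
  if (!length(results)) stop("no results to tabulate")
  if (is.null(names(results)))
    names(results) <- paste0("design_", seq_along(results))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    stopifnot(inherits(r, "optimal_programme"))
    oc <- r$oc
    data.frame(problem = nm, pilot_type = r$design$pilot_type,
               n1 = r$design$n1, n2 = r$design$n2,
               alpha1 = oc$alpha1, beta1 = oc$beta1,
               alpha2 = oc$alpha2, beta2 = oc$beta2,
               alpha_t = oc$alpha_t, beta_t = oc$beta_t,
               eu = r$expected_utility)
  })
  do.call(rbind, rows)
}

#' Render a programme table as aligned text
#'
#' Probabilities are printed to 3 decimal places and expected utilities to
#' 5, matching the precision conventions of the field's reporting tables.
#'
#' @param tab A data frame from [programme_table()].
#' @return Character vector of lines, invisibly; printed as a side effect.
#' @export
format_programme_table <- function(tab) {
  stopifnot(is.data.frame(tab), nrow(tab) >= 1)
  shown <- tab
  for (cl in c("alpha1", "beta1", "alpha2", "beta2", "alpha_t", "beta_t"))
    shown[[cl]] <- sprintf("%.3f", tab[[cl]])
  shown$eu <- sprintf("%.5f", tab$eu)
  txt <- utils::capture.output(print(shown, row.names = FALSE))
  cat(txt, sep = "\n")
  invisible(txt)
}
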