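#' Regret of a proposed design under a perturbed scenario
#'
#' Measures how much is lost by keeping a fixed proposed design when the
#' prior or utility parameters turn out to differ from those used to derive
#' it. The locally optimal design is found under the perturbed scenario, and
#' the gap between its expected utility and the proposed design's (both
#' computed under the perturbed scenario) is converted to
#' participant-equivalent units with the perturbed scenario's `rho` and
#' `kn` (see [regret_in_participants()]).
#'
#' @param proposed A `programme_design` (kept fixed).
#' @param perturbed_scenario A `trial_scenario` with the perturbed
#'   parameters.
#' @param constraints A [design_constraints()] under which the local optimum
#'   is sought; the proposed design should be feasible under them.
#' @param extra_starts Optional warm-start list passed to the optimiser.
#' @return A list of class `regret_cell`: `regret` (participants, floored at
#'   0 with tolerance 1e-6), `eu_proposed`, `eu_optimal`, `local_optimum`
#'   (an `optimal_programme`).
#' @export
regret_at <- function(proposed, perturbed_scenario,
                      constraints = design_constraints(),
                      extra_starts = NULL) {
  stopifnot(inherits(proposed, "programme_design"),
            inherits(perturbed_scenario, "trial_scenario"))
  opt <- optimise_programme(perturbed_scenario, constraints,
                            extra_starts = extra_starts)
  eu_prop <- expected_utility(proposed, perturbed_scenario)
  # the optimiser can only improve on any feasible design; clamp tiny
  # negative gaps arising from numerical profiling error
  u_best <- max(opt$expected_utility, eu_prop)
  reg <- regret_in_participants(u_best, eu_prop, perturbed_scenario$utility)
  if (reg < -1e-6) stop("negative regret beyond numerical tolerance")
  structure(list(regret = max(reg, 0),
                 eu_proposed = eu_prop,
                 eu_optimal = opt$expected_utility,
                 local_optimum = opt),
            class = "regret_cell")
}

#' Regret surface over a two-parameter grid
#'
#' Evaluates [regret_at()] over the Cartesian grid of two varied scenario
#' parameters, warm-starting each cell's optimisation from its neighbour in
#' the inner loop. Supported parameter names: `"m"`, `"s"` (prior mean and
#' SD), `"rho"` (risk attitude) and `"d_bar"` (sampling cost; re-deriving
#' the value weights requires the base elicitation, so supply
#' `elicitation`).
#'
#' @param proposed A `programme_design`.
#' @param base_scenario The scenario the proposed design was derived for.
#' @param param1,param2 Names of the two varied parameters.
#' @param grid1,grid2 Numeric vectors of values for each.
#' @param constraints A [design_constraints()].
#' @param elicitation The base [elicitation()]; required when `d_bar` is
#'   varied (the other two elicited quantities are held fixed).
#' @return A long-format data frame with columns `param1`, `param2` (named
#'   after the varied parameters), `regret`, `n1`, `n2`, `alpha1`, `alpha2`
#'   of the local optimum, and a `failed` flag.
#' @export
regret_surface <- function(proposed, base_scenario, param1, param2,
                           grid1, grid2,
                           constraints = design_constraints(),
                           elicitation = NULL) {
  ok <- c("m", "s", "rho", "d_bar")
  stopifnot(param1 %in% ok, param2 %in% ok, param1 != param2)
  if (("d_bar" %in% c(param1, param2)) && is.null(elicitation))
    stop("varying d_bar requires the base elicitation")
  modify <- function(sc, par, val) {
    if (par == "m") sc$prior$m <- val
    else if (par == "s") sc$prior$s <- val
    else if (par == "rho")
      sc$utility <- utility_params(sc$utility$weights, val)
    else {
      e <- elicitation
      w <- derive_weights(elicitation(val, e$d_hat, e$n_star))
      sc$utility <- utility_params(w, sc$utility$rho)
    }
    sc
  }
  rows <- list()
  for (v1 in grid1) {
    warm <- NULL
    for (v2 in grid2) {
      sc <- modify(modify(base_scenario, param1, v1), param2, v2)
      cell <- tryCatch(
        regret_at(proposed, sc, constraints, extra_starts = warm),
        error = function(e) e)
      if (inherits(cell, "error")) {
        rows[[length(rows) + 1L]] <-
          data.frame(v1 = v1, v2 = v2, regret = NA, n1 = NA, n2 = NA,
                     alpha1 = NA, alpha2 = NA, failed = TRUE)
        warm <- NULL
        next
      }
      warm <- list(warm_start_par(cell$local_optimum, sc))
      oc <- cell$local_optimum$oc
      rows[[length(rows) + 1L]] <-
        data.frame(v1 = v1, v2 = v2, regret = cell$regret,
                   n1 = cell$local_optimum$design$n1,
                   n2 = cell$local_optimum$design$n2,
                   alpha1 = oc$alpha1, alpha2 = oc$alpha2, failed = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1:2] <- c(param1, param2)
  out
}
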