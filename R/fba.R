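# Flux balance analysis and flux variability on top of the LP layer.

#' Flux balance analysis
#'
#' Maximizes (or minimizes) a linear objective over the flux polytope
#' `{ r : N r = 0, lb <= r <= ub }`. Infeasible and unsolved problems are
#' reported through the `status` field, never as silent zeros.
#'
#' @param model A [stoich_model()].
#' @param objective A reaction id or named coefficient vector; defaults to
#'   the model's stored objective.
#' @param sense `"max"` or `"min"`.
#' @return A `flux_distribution`: a tibble with columns `reaction` and
#'   `flux`, plus attributes `objective_value` and `status`. Use
#'   [glance()] for a one-row summary.
#' @export
fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  coef <- if (is.null(objective)) model$reactions$objective
          else objective_coefs(model, objective)
  if (all(coef == 0)) stop("no objective set; supply `objective`")
  N <- stoich_matrix(model)
  res <- solve_lp(coef, N, rep(0, nrow(N)),
                  model$reactions$lb, model$reactions$ub, sense)
  new_flux_distribution(model$reactions$id, res)
}

new_flux_distribution <- function(rxn_ids, res) {
  out <- tibble::tibble(reaction = rxn_ids, flux = res$x)
  structure(out,
            objective_value = res$objval,
            status = res$status,
            class = c("flux_distribution", class(out)))
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> status:", attr(x, "status"),
      " objective:", format(attr(x, "objective_value"), digits = 7), "\n")
  NextMethod()
}

#' @rdname fba
#' @param x A `flux_distribution`.
#' @param ... Unused.
#' @method glance flux_distribution
#' @export
glance.flux_distribution <- function(x, ...) {
  tibble::tibble(objective_value = attr(x, "objective_value"),
                 status = attr(x, "status"))
}

#' Extremum of a single flux under fixed fluxes
#'
#' Flux-variability-style query: minimize or maximize one reaction's rate
#' while holding a set of other fluxes fixed (e.g., the community growth
#' rate), used for minimum product-formation rates.
#'
#' @param model A [stoich_model()].
#' @param target Reaction id, or a named coefficient vector for a linear
#'   combination of fluxes.
#' @param fixed Named numeric vector: reaction ids to pin (`lb = ub =`
#'   value).
#' @param sense `"min"` or `"max"`.
#' @return A one-row tibble with `value` and `status`.
#' @export
flux_extremum <- function(model, target, fixed = NULL,
                          sense = c("min", "max")) {
  sense <- match.arg(sense)
  if (length(fixed)) {
    model <- set_bounds(model, names(fixed), lb = unname(fixed),
                        ub = unname(fixed))
  }
  coef <- objective_coefs(model, target)
  N <- stoich_matrix(model)
  res <- solve_lp(coef, N, rep(0, nrow(N)),
                  model$reactions$lb, model$reactions$ub, sense)
  tibble::tibble(value = res$objval, status = res$status)
}

#' Maximum biomass yield on a substrate
#'
#' True maximum yield (gDW per mmol substrate) when `fixed_growth` is
#' absent: the maintenance flux is relaxed to zero, the substrate uptake is
#' capped at one unit and biomass production maximized, so the returned value
#' excludes substrate burnt for maintenance. With `fixed_growth = mu` the
#' growth-rate-dependent apparent yield is returned instead: `mu` divided by
#' the minimal substrate uptake that supports growth at `mu` with the
#' maintenance demand active.
#'
#' @param model A [stoich_model()] (single species).
#' @param biomass_rxn Reaction id of the biomass synthesis reaction.
#' @param substrate_rxn Id(s) of the uptake reaction(s) for the substrate of
#'   interest; their summed flux is the uptake rate.
#' @param blocked Reaction ids to shut off (uptakes of competing
#'   substrates), `ub` set to 0.
#' @param fixed_growth Optional growth rate (1/h).
#' @param maintenance_rxn Optional id of the ATP-maintenance reaction whose
#'   lower bound is relaxed to zero for the true yield.
#' @return Yield in gDW/mmol, or `NA` with a message attribute if the
#'   substrate cannot support growth.
#' @export
max_yield <- function(model, biomass_rxn, substrate_rxn, blocked = character(),
                      fixed_growth = NULL, maintenance_rxn = NULL) {
  if (length(blocked)) model <- set_bounds(model, blocked, ub = 0)
  if (is.null(fixed_growth)) {
    if (!is.null(maintenance_rxn)) {
      model <- set_bounds(model, maintenance_rxn, lb = 0)
    }
    # cap summed substrate uptake at 1 mmol/gDW/h and maximize biomass;
    # linearity makes the yield scale-free
    rxns <- model$reactions
    coef <- objective_coefs(model, biomass_rxn)
    upt_row <- objective_coefs(
      model, stats::setNames(rep(1, length(substrate_rxn)), substrate_rxn))
    N <- stoich_matrix(model)
    res <- solve_lp(coef, N, rep(0, nrow(N)), rxns$lb, rxns$ub, "max",
                    A_leq = matrix(upt_row, 1L), b_leq = 1)
    if (res$status != "optimal" || res$objval <= 1e-12) {
      return(structure(NA_real_, message = "substrate does not support growth"))
    }
    return(res$objval / sum(upt_row * res$x))
  }
  model <- set_bounds(model, biomass_rxn, lb = fixed_growth, ub = fixed_growth)
  coef <- stats::setNames(rep(1, length(substrate_rxn)), substrate_rxn)
  ext <- flux_extremum(model, coef, sense = "min")
  if (ext$status != "optimal" || ext$value <= 1e-12) {
    return(structure(NA_real_, message = "substrate does not support growth"))
  }
  fixed_growth / ext$value
}

#' Write a flux distribution to CSV
#'
#' Two columns, `reaction_id` and `flux`.
#'
#' @param fluxes A `flux_distribution`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(fluxes, path) {
  readr::write_csv(
    tibble::tibble(reaction_id = fluxes$reaction,
                   flux = signif(fluxes$flux, 6)),
    path)
  invisible(path)
}
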