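# Hierarchical (lexicographic) community optimization.
#
# Primary objective: maximize the community growth rate mu_C at a given
# composition F. Secondary objective: minimize the yield-weighted total
# substrate consumption
#     z = sum over (species i, substrate S_i) of  r_Si * Ymax_{Xi/Si}(mu_C)
# where Ymax is the species' maximum biomass yield on that substrate at the
# fixed growth rate, computed in the single-species model with all its other
# substrates blocked and the maintenance demand active. z is the smallest
# total biomass synthesis rate (gDW_C/gDW_C/h) the consumed substrate could
# have supported; the optimality degree
#     OptDeg = mu_C / z_opt
# equals one exactly when every species converts substrate to biomass at
# maximum yield, and is below one when some species must waste substrate to
# keep the community balanced. Values slightly above one are possible only
# when a species co-consumes several substrates whose combination beats the
# per-substrate maxima.

#' Maximum community growth rate at a composition
#'
#' @param template A [assemble_community()] template.
#' @param fractions Composition vector.
#' @return One-row tibble: `mu_c_opt` (0 when only zero growth is feasible,
#'   `NA` when the composition admits no feasible flux at all) and
#'   `feasible`.
#' @export
max_community_growth <- function(template, fractions) {
  model <- instantiate_community(template, fractions)
  sol <- fba(model, objective = template$community_rxn, sense = "max")
  if (attr(sol, "status") != "optimal") {
    return(tibble::tibble(mu_c_opt = NA_real_, feasible = FALSE))
  }
  tibble::tibble(mu_c_opt = attr(sol, "objective_value"), feasible = TRUE)
}

# Block all consumption of a boundary metabolite in a single-species model.
block_uptake <- function(model, metabolite) {
  st <- model$stoichiometry
  rows <- st[st$metabolite == metabolite, ]
  cons <- rows$reaction[rows$coefficient < 0]
  if (length(cons)) model <- set_bounds(model, cons, ub = 0)
  prod_rev <- rows$reaction[rows$coefficient > 0]
  prod_rev <- intersect(
    prod_rev, model$reactions$id[model$reactions$lb < 0])
  if (length(prod_rev)) model <- set_bounds(model, prod_rev, lb = 0)
  model
}

# Net consumption (uptake) of a boundary metabolite as objective
# coefficients over all reactions.
uptake_coefs <- function(model, metabolite) {
  st <- model$stoichiometry
  rows <- st[st$metabolite == metabolite, ]
  coef <- numeric(nrow(model$reactions))
  coef[match(rows$reaction, model$reactions$id)] <- -rows$coefficient
  coef
}

# Single-species model with the spec's maintenance demand and rate caps
# applied (per gDW of the species).
single_species_model <- function(spec) {
  m <- spec$model
  if (!is.null(spec$maintenance_rxn)) {
    m <- set_bounds(m, spec$maintenance_rxn, lb = spec$atp_maintenance)
  }
  if (length(spec$rate_caps)) {
    m <- set_bounds(m, names(spec$rate_caps), ub = unname(spec$rate_caps))
  }
  m
}

#' Species maximum biomass yield at a fixed growth rate
#'
#' Computed in the single-species model: growth fixed to `mu_c`, all other
#' declared substrates blocked, maintenance active; the yield is `mu_c`
#' divided by the minimal net uptake of the substrate. With zero maintenance
#' the yield is growth-rate independent and equals the true maximum yield.
#'
#' @param spec A [species_spec()].
#' @param substrate One of the spec's substrate ids.
#' @param mu_c Growth rate (1/h), must be > 0.
#' @return Yield in gDW/mmol, or `NA` if the substrate cannot support
#'   growth at `mu_c`.
#' @export
species_yield_at <- function(spec, substrate, mu_c) {
  stopifnot(substrate %in% spec$substrates, mu_c > 0)
  m <- single_species_model(spec)
  for (other in setdiff(spec$substrates, substrate)) {
    m <- block_uptake(m, other)
  }
  m <- set_bounds(m, spec$biomass_rxn, lb = mu_c, ub = mu_c)
  coef <- uptake_coefs(m, substrate)
  N <- stoich_matrix(m)
  res <- solve_lp(coef, N, rep(0, nrow(N)), m$reactions$lb, m$reactions$ub,
                  "min")
  if (res$status != "optimal" || res$objval <= 1e-12) return(NA_real_)
  mu_c / res$objval
}

#' Maximum-yield table for all (species, substrate) pairs
#'
#' @param template A community template.
#' @param mu_c The community growth rate the yields refer to.
#' @return Tibble `species`, `substrate`, `yield`, `mu_c`; unavailable
#'   substrates (cannot support growth at `mu_c`) carry `NA`.
#' @export
yield_table <- function(template, mu_c) {
  purrr::map_dfr(template$specs, function(spec) {
    if (!length(spec$substrates)) return(NULL)
    tibble::tibble(
      species = spec$species_id,
      substrate = spec$substrates,
      yield = vapply(spec$substrates, function(s) {
        species_yield_at(spec, s, mu_c)
      }, numeric(1)),
      mu_c = mu_c)
  })
}

#' Minimal yield-weighted substrate consumption at fixed growth
#'
#' The secondary LP of the hierarchical optimization: growth pinned to
#' `mu_c`, objective `sum(r_Si * Ymax_i)` minimized over the community flux
#' polytope. Substrates whose yield is `NA` (unavailable at `mu_c`) are
#' omitted from the objective.
#'
#' @param template A community template.
#' @param fractions Composition vector.
#' @param mu_c Community growth rate to pin.
#' @param yields A [yield_table()]; computed at `mu_c` if missing.
#' @return List with `z_opt`, `status`, `fluxes` (a `flux_distribution`)
#'   and `uptakes` (per species/substrate uptake rates, mmol/gDW_C/h).
#' @export
min_weighted_substrate <- function(template, fractions, mu_c, yields = NULL) {
  if (is.null(yields)) yields <- yield_table(template, mu_c)
  model <- instantiate_community(template, fractions)
  model <- set_bounds(model, template$community_rxn, lb = mu_c, ub = mu_c)

  wt <- dplyr::inner_join(template$uptakes, yields,
                          by = c("species", "substrate"))
  wt <- wt[!is.na(wt$yield), ]
  coef <- numeric(nrow(model$reactions))
  if (nrow(wt)) {
    idx <- match(wt$reaction, model$reactions$id)
    coef[idx] <- coef[idx] + wt$yield
  }
  N <- stoich_matrix(model)
  res <- solve_lp(coef, N, rep(0, nrow(N)), model$reactions$lb,
                  model$reactions$ub, "min")
  fluxes <- new_flux_distribution(model$reactions$id, res)
  upt <- NULL
  if (res$status == "optimal" && nrow(template$uptakes)) {
    upt <- template$uptakes
    upt$flux <- res$x[match(upt$reaction, model$reactions$id)]
    upt <- dplyr::summarise(dplyr::group_by(upt, .data$species,
                                            .data$substrate),
                            uptake = sum(.data$flux), .groups = "drop")
  }
  list(z_opt = res$objval, status = res$status, fluxes = fluxes,
       uptakes = upt)
}

#' Hierarchical optimization result at a composition
#'
#' Runs the full two-level procedure: maximize `mu_C` (or accept a fixed
#' value), recompute the yield table at that rate, then minimize the
#' yield-weighted substrate consumption; `OptDeg = mu_C / z_opt`.
#'
#' @param template A community template.
#' @param fractions Composition vector.
#' @param mu_c `"max"` (default) or a fixed community growth rate.
#' @return An `optdeg_result`; see [glance.optdeg_result()] and
#'   [tidy.optdeg_result()].
#' @export
optimality_degree <- function(template, fractions, mu_c = "max") {
  fr <- community_composition(fractions, template$species$species)
  if (identical(mu_c, "max")) {
    g <- max_community_growth(template, fr)
    mu <- g$mu_c_opt
    if (!g$feasible || is.na(mu) || mu <= 1e-9) {
      return(new_optdeg_result(fr, mu_c_opt = if (isTRUE(g$feasible)) 0 else
        NA_real_, feasible = FALSE))
    }
  } else {
    stopifnot(is.numeric(mu_c), mu_c >= 0)
    mu <- mu_c
    if (mu <= 1e-9) {
      return(new_optdeg_result(fr, mu_c_opt = 0, feasible = FALSE))
    }
  }
  yields <- yield_table(template, mu)
  z <- min_weighted_substrate(template, fr, mu, yields)
  if (z$status != "optimal") {
    return(new_optdeg_result(fr, mu_c_opt = mu, feasible = FALSE))
  }
  new_optdeg_result(fr, mu_c_opt = mu, z_opt = z$z_opt,
                    optdeg = mu / z$z_opt, fluxes = z$fluxes,
                    uptakes = z$uptakes, yields = yields, feasible = TRUE)
}

new_optdeg_result <- function(fractions, mu_c_opt = NA_real_,
                              z_opt = NA_real_, optdeg = NA_real_,
                              fluxes = NULL, uptakes = NULL, yields = NULL,
                              feasible = FALSE) {
  structure(list(fractions = fractions, mu_c_opt = mu_c_opt, z_opt = z_opt,
                 optdeg = optdeg, fluxes = fluxes, uptakes = uptakes,
                 yields = yields, feasible = feasible),
            class = "optdeg_result")
}

#' @export
print.optdeg_result <- function(x, ...) {
  cat("<optdeg_result> F = (",
      paste(sprintf("%s=%.3f", names(x$fractions), x$fractions),
            collapse = ", "), ")\n", sep = "")
  if (x$feasible) {
    cat(sprintf("  mu_C = %.6g 1/h   z = %.6g   OptDeg = %.6g\n",
                x$mu_c_opt, x$z_opt, x$optdeg))
  } else {
    cat("  infeasible (mu_C_opt =", x$mu_c_opt, ")\n")
  }
  invisible(x)
}

#' One-row summary of a hierarchical optimization
#'
#' @param x An `optdeg_result`.
#' @param ... Unused.
#' @return Tibble with the composition, `mu_c_opt`, `z_opt`, `optdeg` and
#'   `feasible`.
#' @method glance optdeg_result
#' @export
glance.optdeg_result <- function(x, ...) {
  fr <- tibble::as_tibble(as.list(stats::setNames(
    x$fractions, paste0("F_", names(x$fractions)))))
  dplyr::bind_cols(fr, tibble::tibble(
    mu_c_opt = x$mu_c_opt, z_opt = x$z_opt, optdeg = x$optdeg,
    feasible = x$feasible))
}

#' Per-substrate uptake rates of a hierarchical optimization
#'
#' @param x An `optdeg_result`.
#' @param ... Unused.
#' @return Tibble `species`, `substrate`, `uptake` (mmol/gDW_C/h), `yield`.
#' @method tidy optdeg_result
#' @export
tidy.optdeg_result <- function(x, ...) {
  if (is.null(x$uptakes)) {
    return(tibble::tibble(species = character(), substrate = character(),
                          uptake = numeric(), yield = numeric()))
  }
  dplyr::left_join(x$uptakes, x$yields[, c("species", "substrate", "yield")],
                   by = c("species", "substrate"))
}
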