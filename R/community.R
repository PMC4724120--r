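# Balanced-growth community assembly.
#
# Each species model becomes a namespaced compartment; metabolites the
# species trade are merged into a shared exchange pool; each species biomass
# reaction produces one unit of a species biomass metabolite BM_<i>, and a
# community biomass reaction consumes F_i units of every BM_<i> to produce
# one unit of community biomass BM_C (a boundary metabolite). The BM_<i>
# balance then forces r_BMi = F_i * mu_C at steady state: every species
# grows at the common community growth rate mu_C with abundance F_i.
# Species-specific capacity bounds (uptake caps, ATP maintenance) refer to
# gDW of that species and are multiplied by F_i when a composition is
# instantiated, so that all fluxes in the community model are per gDW of
# total community biomass.

#' Describe one species for community assembly
#'
#' @param model A [stoich_model()] of the species. Boundary metabolites
#'   shared with other species (same id) become pool metabolites.
#' @param species_id Short unique label; used as a namespacing suffix.
#' @param biomass_rxn Id of the biomass synthesis reaction. It must produce
#'   exactly one unit of a single (biomass) metabolite.
#' @param substrates Ids of the boundary metabolites this species consumes
#'   that count as substrates in the yield-weighted secondary objective.
#' @param atp_maintenance Non-growth-associated ATP demand,
#'   mmol ATP/gDW/h, imposed as the lower bound of `maintenance_rxn`.
#' @param maintenance_rxn Id of the ATP-hydrolysis reaction (required when
#'   `atp_maintenance > 0`).
#' @param rate_caps Named numeric vector: reaction id -> capacity cap (per
#'   gDW of this species); these upper bounds are scaled by the species
#'   fraction in the community.
#' @return A `species_spec` object.
#' @export
species_spec <- function(model, species_id, biomass_rxn,
                         substrates = character(),
                         atp_maintenance = 0, maintenance_rxn = NULL,
                         rate_caps = NULL) {
  stopifnot(inherits(model, "stoich_model"),
            is.character(species_id), length(species_id) == 1L,
            atp_maintenance >= 0)
  if (!biomass_rxn %in% model$reactions$id) {
    stop("biomass reaction '", biomass_rxn, "' not in model")
  }
  prod <- model$stoichiometry[
    model$stoichiometry$reaction == biomass_rxn &
      model$stoichiometry$coefficient > 0, ]
  if (nrow(prod) != 1L || abs(prod$coefficient - 1) > 1e-12) {
    stop("biomass reaction '", biomass_rxn,
         "' must produce exactly 1 unit of a single biomass metabolite")
  }
  if (atp_maintenance > 0 && is.null(maintenance_rxn)) {
    stop("atp_maintenance > 0 requires maintenance_rxn")
  }
  if (!is.null(maintenance_rxn) &&
      !maintenance_rxn %in% model$reactions$id) {
    stop("maintenance reaction '", maintenance_rxn, "' not in model")
  }
  if (length(rate_caps)) {
    stopifnot(!is.null(names(rate_caps)), all(rate_caps >= 0))
    missing <- setdiff(names(rate_caps), model$reactions$id)
    if (length(missing)) {
      stop("rate_caps reference unknown reactions: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(model = model, species_id = species_id,
                 biomass_rxn = biomass_rxn, biomass_met = prod$metabolite,
                 substrates = substrates,
                 atp_maintenance = atp_maintenance,
                 maintenance_rxn = maintenance_rxn,
                 rate_caps = rate_caps),
            class = "species_spec")
}

#' Accumulation policy for pool metabolites
#'
#' Every metabolite traded through the exchange pool is either `closed`
#' (must be fully consumed within the community, no environment link — e.g.
#' hydrogen and formate in syntrophic methanogenesis), `accumulating`
#' (export to the environment allowed — e.g. acetate, CO2, methane) or
#' `medium` (uptake from the environment allowed — the primary substrate).
#'
#' @param closed,accumulating,medium Character vectors of boundary
#'   metabolite ids (as used in the species models).
#' @return A tibble with columns `metabolite`, `policy`.
#' @export
exchange_policy <- function(closed = character(), accumulating = character(),
                            medium = character()) {
  pol <- tibble::tibble(
    metabolite = c(closed, accumulating, medium),
    policy = c(rep("closed", length(closed)),
               rep("accumulating", length(accumulating)),
               rep("medium", length(medium))))
  if (anyDuplicated(pol$metabolite)) {
    stop("metabolite assigned more than one policy: ",
         paste(unique(pol$metabolite[duplicated(pol$metabolite)]),
               collapse = ", "))
  }
  pol
}

ns_suffix <- function(x, sp) paste0(x, "_", sp)

#' Assemble species models into a community template
#'
#' Internal metabolites and reactions are namespaced with `_<species_id>`;
#' boundary metabolites listed in the policy become `<id>_pool` metabolites
#' shared between species and connected to the environment according to
#' their policy (split into irreversible uptake and export reactions so that
#' substrate uptake fluxes are nonnegative). The community biomass reaction
#' is created with placeholder composition; use [instantiate_community()] to
#' fix a composition `F`.
#'
#' @param species List of [species_spec()] objects.
#' @param policy An [exchange_policy()] table.
#' @return A `community_model` template.
#' @export
assemble_community <- function(species, policy) {
  if (inherits(species, "species_spec")) species <- list(species)
  ids <- vapply(species, function(s) s$species_id, "")
  if (anyDuplicated(ids)) stop("species ids must be unique")

  met_list <- list(); rxn_list <- list(); st_list <- list()
  uptake_list <- list(); scaled_list <- list(); sp_rxn_list <- list()
  species_tab <- list()
  pool_seen <- character(0)

  for (s in species) {
    sp <- s$species_id
    m <- s$model
    mets <- m$metabolites
    is_pool <- mets$boundary & mets$id %in% policy$metabolite
    is_bm <- mets$id == s$biomass_met
    new_id <- ifelse(is_pool, paste0(mets$id, "_pool"),
              ifelse(is_bm, paste0("BM_", sp), ns_suffix(mets$id, sp)))
    rename <- stats::setNames(new_id, mets$id)
    pool_seen <- union(pool_seen, mets$id[is_pool])

    mets2 <- tibble::tibble(
      id = new_id,
      name = mets$name,
      compartment = ifelse(is_pool, "pool",
                    ifelse(is_bm, "biomass", ns_suffix(mets$compartment, sp))),
      boundary = mets$boundary & !is_pool & !is_bm)

    rxns <- m$reactions
    rxns$id <- ns_suffix(rxns$id, sp)
    rxns$objective <- 0
    st <- m$stoichiometry
    st$reaction <- ns_suffix(st$reaction, sp)
    st$metabolite <- rename[st$metabolite]

    # split reversible reactions that touch a pool metabolite into
    # irreversible forward/backward halves (uptake >= 0, export >= 0)
    pool_ids <- new_id[is_pool]
    touches_pool <- rxns$id %in% unique(st$reaction[st$metabolite %in% pool_ids])
    to_split <- which(touches_pool & rxns$lb < 0)
    if (length(to_split)) {
      for (i in to_split) {
        fwd <- rxns[i, ]; bwd <- rxns[i, ]
        bwd$id <- paste0(rxns$id[i], "_rev")
        bwd$name <- paste0(rxns$name[i], " (reverse)")
        fwd$lb <- 0; fwd$reversible <- FALSE
        bwd$lb <- 0; bwd$ub <- -rxns$lb[i]; bwd$reversible <- FALSE
        st_rev <- st[st$reaction == rxns$id[i], ]
        st_rev$reaction <- bwd$id
        st_rev$coefficient <- -st_rev$coefficient
        st <- dplyr::bind_rows(st, st_rev)
        rxn_extra <- bwd
        rxns <- dplyr::bind_rows(rxns, rxn_extra)
        rxns[i, ] <- fwd
      }
    }

    # registry of species-specific (per-gDW_i) bounds to scale by F_i
    sc <- NULL
    if (length(s$rate_caps)) {
      sc <- tibble::tibble(species = sp,
                           reaction = ns_suffix(names(s$rate_caps), sp),
                           bound = "ub", base = unname(s$rate_caps))
    }
    if (!is.null(s$maintenance_rxn)) {
      sc <- dplyr::bind_rows(sc, tibble::tibble(
        species = sp, reaction = ns_suffix(s$maintenance_rxn, sp),
        bound = "lb", base = s$atp_maintenance))
    }
    if (!is.null(sc)) scaled_list[[sp]] <- sc

    # uptake transports per declared substrate (consume the pool metabolite)
    if (length(s$substrates)) {
      up <- list()
      for (sub in s$substrates) {
        pool_id <- paste0(sub, "_pool")
        cand <- st$reaction[st$metabolite == pool_id & st$coefficient < 0]
        cand <- unique(cand)
        if (!length(cand)) {
          stop("species '", sp, "' declares substrate '", sub,
               "' but has no transport consuming it")
        }
        up[[sub]] <- tibble::tibble(species = sp, substrate = sub,
                                    reaction = cand)
      }
      uptake_list[[sp]] <- dplyr::bind_rows(up)
    }

    sp_rxn_list[[sp]] <- tibble::tibble(species = sp, reaction = rxns$id)
    species_tab[[sp]] <- tibble::tibble(
      species = sp,
      biomass_rxn = ns_suffix(s$biomass_rxn, sp),
      biomass_met = paste0("BM_", sp),
      atp_maintenance = s$atp_maintenance,
      maintenance_rxn = if (is.null(s$maintenance_rxn)) NA_character_ else
        ns_suffix(s$maintenance_rxn, sp))
    met_list[[sp]] <- mets2
    rxn_list[[sp]] <- rxns
    st_list[[sp]] <- st
  }

  mets <- dplyr::distinct(dplyr::bind_rows(met_list), .data$id,
                          .keep_all = TRUE)
  rxns <- dplyr::bind_rows(rxn_list)
  st <- dplyr::bind_rows(st_list)

  unused <- setdiff(policy$metabolite, pool_seen)
  if (length(unused)) {
    stop("policy metabolites with no species transport: ",
         paste(unused, collapse = ", "))
  }

  # environment links per policy
  env_rxns <- list(); env_st <- list()
  for (i in seq_len(nrow(policy))) {
    met <- policy$metabolite[i]
    pool_id <- paste0(met, "_pool")
    if (policy$policy[i] == "medium") {
      rid <- paste0("ENV_upt_", met)
      env_rxns[[rid]] <- tibble::tibble(
        id = rid, name = paste("environment uptake of", met),
        reversible = FALSE, lb = 0, ub = DEFAULT_UB, objective = 0)
      env_st[[rid]] <- tibble::tibble(reaction = rid, metabolite = pool_id,
                                      coefficient = 1)
    } else if (policy$policy[i] == "accumulating") {
      rid <- paste0("ENV_exp_", met)
      env_rxns[[rid]] <- tibble::tibble(
        id = rid, name = paste("environment export of", met),
        reversible = FALSE, lb = 0, ub = DEFAULT_UB, objective = 0)
      env_st[[rid]] <- tibble::tibble(reaction = rid, metabolite = pool_id,
                                      coefficient = -1)
    }
  }
  rxns <- dplyr::bind_rows(rxns, dplyr::bind_rows(env_rxns))
  st <- dplyr::bind_rows(st, dplyr::bind_rows(env_st))

  # community biomass: F_i * BM_i -> 1 BM_C (placeholder F = 1/n)
  species_tab <- dplyr::bind_rows(species_tab)
  n <- nrow(species_tab)
  mets <- dplyr::bind_rows(mets, tibble::tibble(
    id = "BM_community", name = "community biomass", compartment = "biomass",
    boundary = TRUE))
  rxns <- dplyr::bind_rows(rxns, tibble::tibble(
    id = "BM_community", name = "community biomass synthesis",
    reversible = FALSE, lb = 0, ub = DEFAULT_UB, objective = 1))
  st <- dplyr::bind_rows(st, tibble::tibble(
    reaction = "BM_community",
    metabolite = c(species_tab$biomass_met, "BM_community"),
    coefficient = c(rep(-1 / n, n), 1)))

  structure(
    list(model = stoich_model(mets, rxns, st),
         species = species_tab,
         specs = stats::setNames(species, ids),
         uptakes = dplyr::bind_rows(uptake_list),
         scaled = dplyr::bind_rows(scaled_list),
         species_reactions = dplyr::bind_rows(sp_rxn_list),
         policy = policy,
         community_rxn = "BM_community"),
    class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", nrow(x$species), " species: ",
      paste(x$species$species, collapse = ", "), "\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Validate a community composition vector
#'
#' Fractions of community biomass per species: each in `[0, 1]`, summing
#' to one.
#'
#' @param fractions Numeric vector, optionally named by species id.
#' @param species Optional species ids to check names/length against.
#' @return The (named) fraction vector.
#' @export
community_composition <- function(fractions, species = NULL) {
  if (!is.null(species)) {
    if (is.null(names(fractions))) {
      stopifnot(length(fractions) == length(species))
      names(fractions) <- species
    } else {
      stopifnot(setequal(names(fractions), species))
      fractions <- fractions[species]
    }
  }
  if (any(fractions < -1e-12) || any(fractions > 1 + 1e-12)) {
    stop("fractions must lie in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")")
  }
  pmin(pmax(fractions, 0), 1)
}

#' Instantiate a community model at a fixed composition
#'
#' Sets the community biomass stoichiometry to `F`, multiplies every
#' registered species-specific bound (rate caps, maintenance lower bound) by
#' the species fraction, and forces all fluxes of species with `F_i = 0` to
#' zero.
#'
#' @param template A [assemble_community()] result.
#' @param fractions Composition vector (see [community_composition()]).
#' @return A plain [stoich_model()] ready for [fba()].
#' @export
instantiate_community <- function(template, fractions) {
  fr <- community_composition(fractions, template$species$species)
  model <- template$model
  st <- model$stoichiometry
  comm <- st$reaction == template$community_rxn & st$metabolite != "BM_community"
  idx <- match(st$metabolite[comm], template$species$biomass_met)
  st$coefficient[comm] <- -fr[template$species$species[idx]]
  model$stoichiometry <- st

  if (nrow(template$scaled)) {
    for (i in seq_len(nrow(template$scaled))) {
      row <- template$scaled[i, ]
      f <- fr[[row$species]]
      if (row$bound == "ub") {
        model <- set_bounds(model, row$reaction, ub = row$base * f)
      } else if (row$bound == "lb") {
        model <- set_bounds(model, row$reaction, lb = row$base * f)
      } else {
        model <- set_bounds(model, row$reaction, lb = row$base * f,
                            ub = row$base * f)
      }
    }
  }

  zero_sp <- names(fr)[fr == 0]
  if (length(zero_sp)) {
    rz <- template$species_reactions$reaction[
      template$species_reactions$species %in% zero_sp]
    model <- set_bounds(model, rz, lb = 0, ub = 0)
  }
  model
}
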