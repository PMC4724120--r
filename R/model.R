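# Core data structure: a stoichiometric model is a list of three tibbles.
# Stoichiometry is kept in long (tidy) form; the matrix N is materialized on
# demand. Rows of N cover internal (non-boundary) metabolites only: boundary
# metabolites are allowed to accumulate and are excluded from balancing.

DEFAULT_UB <- 1000

#' Construct a stoichiometric metabolic model
#'
#' A model is three tibbles: metabolites (`id`, `name`, `compartment`,
#' `boundary`), reactions (`id`, `name`, `reversible`, `lb`, `ub`,
#' `objective`) and the stoichiometry in long form (`reaction`, `metabolite`,
#' `coefficient`; negative coefficients consume). Flux units follow the
#' constraint-based convention: mmol/gDW/h for metabolic fluxes, gDW/gDW/h
#' for biomass-producing reactions and 1/h for a community growth reaction.
#'
#' @param metabolites A data frame with at least an `id` column; optional
#'   `name`, `compartment`, `boundary` columns are completed with defaults.
#' @param reactions A data frame with at least an `id` column; optional
#'   `lb`, `ub`, `reversible`, `objective`, `name`. Missing bounds default to
#'   the COBRA convention (-1000, 1000) for reversible and (0, 1000) for
#'   irreversible reactions. If `reversible` is absent it is inferred from
#'   `lb < 0`.
#' @param stoichiometry A data frame `reaction`, `metabolite`, `coefficient`.
#'
#' @return An object of class `stoich_model`.
#' @examples
#' m <- stoich_model(
#'   metabolites = tibble::tibble(id = c("S", "A"),
#'                                boundary = c(TRUE, FALSE)),
#'   reactions = tibble::tibble(id = c("upt", "bio"),
#'                              lb = 0, ub = c(10, 1000),
#'                              objective = c(0, 1)),
#'   stoichiometry = tibble::tibble(
#'     reaction = c("upt", "upt", "bio"),
#'     metabolite = c("S", "A", "A"),
#'     coefficient = c(-1, 1, -20))
#' )
#' fba(m)
#' @export
stoich_model <- function(metabolites, reactions, stoichiometry) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)

  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (!"boundary" %in% names(metabolites)) metabolites$boundary <- FALSE
  metabolites <- metabolites[, c("id", "name", "compartment", "boundary")]

  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  has_lb <- "lb" %in% names(reactions)
  has_ub <- "ub" %in% names(reactions)
  if (!"reversible" %in% names(reactions)) {
    reactions$reversible <- if (has_lb) reactions$lb < 0 else FALSE
  }
  if (!has_lb) {
    reactions$lb <- ifelse(reactions$reversible, -DEFAULT_UB, 0)
  }
  if (!has_ub) reactions$ub <- DEFAULT_UB
  reactions$lb <- ifelse(is.na(reactions$lb),
                         ifelse(reactions$reversible, -DEFAULT_UB, 0),
                         reactions$lb)
  reactions$ub <- ifelse(is.na(reactions$ub), DEFAULT_UB, reactions$ub)
  if (!"objective" %in% names(reactions)) reactions$objective <- 0
  reactions <- reactions[, c("id", "name", "reversible", "lb", "ub",
                             "objective")]

  model <- structure(
    list(metabolites = metabolites,
         reactions = reactions,
         stoichiometry = stoichiometry),
    class = "stoich_model"
  )
  validate_stoich_model(model)
}

validate_stoich_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  st <- model$stoichiometry
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  bad_met <- setdiff(st$metabolite, mets$id)
  if (length(bad_met)) {
    stop("stoichiometry references unknown metabolites: ",
         paste(bad_met, collapse = ", "))
  }
  bad_rxn <- setdiff(st$reaction, rxns$id)
  if (length(bad_rxn)) {
    stop("stoichiometry references unknown reactions: ",
         paste(bad_rxn, collapse = ", "))
  }
  if (any(rxns$lb > rxns$ub)) {
    stop("lb > ub for reactions: ",
         paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "))
  }
  irrev_neg <- !rxns$reversible & rxns$lb < 0
  if (any(irrev_neg)) {
    stop("irreversible reactions with negative lower bound: ",
         paste(rxns$id[irrev_neg], collapse = ", "))
  }
  model
}

#' @export
print.stoich_model <- function(x, ...) {
  n_int <- sum(!x$metabolites$boundary)
  cat("<stoich_model> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (", n_int, " balanced)\n", sep = "")
  obj <- x$reactions$id[x$reactions$objective != 0]
  if (length(obj)) cat("objective:", paste(obj, collapse = " + "), "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' Builds the dense matrix N with one row per internal (non-boundary)
#' metabolite and one column per reaction; `N r = 0` is the steady-state
#' balancing constraint.
#'
#' @param model A [stoich_model()].
#' @param boundary If `TRUE`, include boundary metabolites as rows too
#'   (useful for inspecting net accumulation).
#' @return A numeric matrix with dimnames.
#' @export
stoich_matrix <- function(model, boundary = FALSE) {
  mets <- if (boundary) model$metabolites$id else
    model$metabolites$id[!model$metabolites$boundary]
  rxns <- model$reactions$id
  N <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  st <- model$stoichiometry
  keep <- st$metabolite %in% mets
  N[cbind(match(st$metabolite[keep], mets), match(st$reaction[keep], rxns))] <-
    st$coefficient[keep]
  N
}

#' Modify reaction bounds
#'
#' Returns a copy of the model with bounds of the named reactions replaced.
#' `NA` entries leave the corresponding bound untouched.
#'
#' @param model A [stoich_model()].
#' @param reaction Character vector of reaction ids.
#' @param lb,ub Replacement bounds, recycled to `length(reaction)`.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lb = NA, ub = NA) {
  idx <- match(reaction, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reactions: ", paste(reaction[is.na(idx)], collapse = ", "))
  }
  lb <- rep_len(lb, length(idx))
  ub <- rep_len(ub, length(idx))
  model$reactions$lb[idx] <- ifelse(is.na(lb), model$reactions$lb[idx], lb)
  model$reactions$ub[idx] <- ifelse(is.na(ub), model$reactions$ub[idx], ub)
  model
}

#' Set the FBA objective
#'
#' @param model A [stoich_model()].
#' @param objective Either a reaction id (coefficient 1) or a named numeric
#'   vector of coefficients over reaction ids.
#' @return The modified model.
#' @export
set_objective <- function(model, objective) {
  model$reactions$objective <- 0
  coef <- objective_coefs(model, objective)
  model$reactions$objective <- coef
  model
}

objective_coefs <- function(model, objective) {
  rxns <- model$reactions$id
  coef <- numeric(length(rxns))
  if (is.character(objective) && length(objective) == 1L && is.null(names(objective))) {
    i <- match(objective, rxns)
    if (is.na(i)) stop("unknown objective reaction: ", objective)
    coef[i] <- 1
  } else if (is.numeric(objective) && !is.null(names(objective))) {
    i <- match(names(objective), rxns)
    if (anyNA(i)) {
      stop("unknown objective reactions: ",
           paste(names(objective)[is.na(i)], collapse = ", "))
    }
    coef[i] <- unname(objective)
  } else {
    stop("objective must be a reaction id or a named numeric vector")
  }
  coef
}

# Reactions consuming (direction = "in") or producing (direction = "out")
# a metabolite, restricted to irreversible reactions when strict.
reactions_touching <- function(model, metabolite, direction = c("in", "out")) {
  direction <- match.arg(direction)
  st <- model$stoichiometry
  sel <- st$metabolite == metabolite &
    (if (direction == "in") st$coefficient < 0 else st$coefficient > 0)
  unique(st$reaction[sel])
}
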