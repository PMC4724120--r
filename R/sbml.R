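# SBML import/export for the constraint-based subset the package needs:
# compartments, species (with boundaryCondition), reactions with
# stoichiometry, flux bounds and an FBA objective. Written files are SBML
# Level 3 Version 1 with the fbc-v2 package; the reader additionally accepts
# Level 2 files carrying LOWER_BOUND/UPPER_BOUND kinetic-law parameters.

SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# attribute lookup by local name, tolerant of namespace prefixes
xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(at)) == name)
  if (length(hit)) at[[hit[1]]] else NA_character_
}

#' Read a constraint-based model from SBML
#'
#' Supports SBML L3 (fbc flux bounds and objectives) and L2 (kinetic-law
#' `LOWER_BOUND`/`UPPER_BOUND` parameters). Species are flagged as boundary
#' metabolites when `boundaryCondition="true"` or when they live in one of
#' `boundary_compartments`. Reactions without explicit bounds receive the
#' COBRA defaults (-1000, 1000) if reversible and (0, 1000) otherwise, with
#' a warning naming every defaulted reaction.
#'
#' @param path Path to an SBML file.
#' @param boundary_compartments Compartment ids treated as the environment;
#'   their species are boundary metabolites.
#' @return A [stoich_model()].
#' @export
load_sbml <- function(path, boundary_compartments = c("env", "environment")) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model_node, "xml_missing")) {
    stop("malformed SBML: no <model> element in '", path, "'")
  }

  sp_nodes <- xml2::xml_find_all(model_node, ".//listOfSpecies/species")
  mets <- tibble::tibble(
    id = vapply(sp_nodes, xattr, "", name = "id"),
    name = vapply(sp_nodes, function(n) {
      nm <- xattr(n, "name"); if (is.na(nm)) xattr(n, "id") else nm
    }, ""),
    compartment = vapply(sp_nodes, xattr, "", name = "compartment"),
    boundary = vapply(sp_nodes, function(n) {
      isTRUE(tolower(xattr(n, "boundaryCondition")) == "true")
    }, logical(1))
  )
  mets$boundary <- mets$boundary | mets$compartment %in% boundary_compartments

  # global parameters (fbc bound references)
  par_nodes <- xml2::xml_find_all(model_node, "./listOfParameters/parameter")
  pars <- stats::setNames(
    as.numeric(vapply(par_nodes, xattr, "", name = "value")),
    vapply(par_nodes, xattr, "", name = "id"))

  rx_nodes <- xml2::xml_find_all(model_node, ".//listOfReactions/reaction")
  st_list <- vector("list", length(rx_nodes))
  rxn_rows <- vector("list", length(rx_nodes))
  defaulted <- character(0)
  for (k in seq_along(rx_nodes)) {
    rn <- rx_nodes[[k]]
    rid <- xattr(rn, "id")
    if (is.na(rid)) stop("malformed SBML: <reaction> without id in '", path, "'")
    rev_attr <- xattr(rn, "reversible")
    reversible <- is.na(rev_attr) || tolower(rev_attr) == "true"

    reacts <- xml2::xml_find_all(rn, "./listOfReactants/speciesReference")
    prods <- xml2::xml_find_all(rn, "./listOfProducts/speciesReference")
    coef_tab <- function(nodes, sign) {
      if (!length(nodes)) return(NULL)
      tibble::tibble(
        reaction = rid,
        metabolite = vapply(nodes, xattr, "", name = "species"),
        coefficient = sign * vapply(nodes, function(n) {
          s <- xattr(n, "stoichiometry")
          if (is.na(s)) 1 else as.numeric(s)
        }, numeric(1)))
    }
    st_list[[k]] <- dplyr::bind_rows(coef_tab(reacts, -1), coef_tab(prods, 1))

    lb <- ub <- NA_real_
    lb_ref <- xattr(rn, "lowerFluxBound")
    ub_ref <- xattr(rn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(pars)) lb <- pars[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(pars)) ub <- pars[[ub_ref]]
    if (is.na(lb) || is.na(ub)) {
      kl <- xml2::xml_find_all(rn, "./kineticLaw//parameter")
      if (length(kl)) {
        kl_ids <- vapply(kl, xattr, "", name = "id")
        kl_val <- as.numeric(vapply(kl, xattr, "", name = "value"))
        if (is.na(lb) && "LOWER_BOUND" %in% kl_ids) {
          lb <- kl_val[match("LOWER_BOUND", kl_ids)]
        }
        if (is.na(ub) && "UPPER_BOUND" %in% kl_ids) {
          ub <- kl_val[match("UPPER_BOUND", kl_ids)]
        }
      }
    }
    if (is.na(lb) || is.na(ub)) defaulted <- c(defaulted, rid)
    if (is.na(lb)) lb <- if (reversible) -DEFAULT_UB else 0
    if (is.na(ub)) ub <- DEFAULT_UB
    lb <- max(lb, -DEFAULT_UB)
    ub <- min(ub, DEFAULT_UB)
    nm <- xattr(rn, "name")
    rxn_rows[[k]] <- tibble::tibble(
      id = rid, name = if (is.na(nm)) rid else nm,
      reversible = reversible, lb = lb, ub = ub, objective = 0)
  }
  if (length(defaulted)) {
    warning("no flux bounds in SBML for reaction(s) ",
            paste(defaulted, collapse = ", "),
            "; using defaults (-1000,1000)/(0,1000)", call. = FALSE)
  }
  rxns <- dplyr::bind_rows(rxn_rows)

  # active fbc objective, if any
  fo <- xml2::xml_find_all(model_node,
                           ".//*[local-name()='fluxObjective']")
  if (length(fo)) {
    orx <- vapply(fo, xattr, "", name = "reaction")
    oco <- vapply(fo, function(n) {
      cc <- xattr(n, "coefficient"); if (is.na(cc)) 1 else as.numeric(cc)
    }, numeric(1))
    idx <- match(orx, rxns$id)
    if (anyNA(idx)) {
      stop("malformed SBML: fluxObjective references unknown reaction ",
           paste(orx[is.na(idx)], collapse = ", "))
    }
    rxns$objective[idx] <- oco
  }

  st <- dplyr::bind_rows(st_list)
  missing_mets <- setdiff(st$metabolite, mets$id)
  if (length(missing_mets)) {
    stop("malformed SBML: speciesReference to unknown species ",
         paste(missing_mets, collapse = ", "))
  }
  stoich_model(mets, rxns, st)
}

#' Write a model to SBML (Level 3, fbc v2)
#'
#' Bounds are encoded as shared global parameters referenced through
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`; a nonzero objective becomes the
#' active fbc objective. `load_sbml(write_sbml(m))` reproduces stoichiometry,
#' bounds, boundary flags and objective.
#'
#' @param model A [stoich_model()].
#' @param path Output path.
#' @param id Model id attribute.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, id = "model") {
  num <- function(x) sprintf("%.15g", x)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_L3_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = id, "fbc:strict" = "true")

  comps <- unique(model$metabolites$compartment)
  cl <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cc in comps) {
    xml2::xml_add_child(cl, "compartment", id = cc, constant = "true")
  }

  sl <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(
      sl, "species", id = m$id, name = m$name, compartment = m$compartment,
      boundaryCondition = tolower(as.character(m$boundary)),
      hasOnlySubstanceUnits = "false", constant = "false")
  }

  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bid <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)), num(bounds))
  pl <- xml2::xml_add_child(mnode, "listOfParameters")
  for (b in bounds) {
    xml2::xml_add_child(pl, "parameter", id = bid[[num(b)]], value = num(b),
                        constant = "true")
  }

  rl <- xml2::xml_add_child(mnode, "listOfReactions")
  st <- model$stoichiometry
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rn <- xml2::xml_add_child(
      rl, "reaction", id = r$id, name = r$name,
      reversible = tolower(as.character(r$reversible)), fast = "false",
      "fbc:lowerFluxBound" = bid[[num(r$lb)]],
      "fbc:upperFluxBound" = bid[[num(r$ub)]])
    rows <- st[st$reaction == r$id, ]
    reac <- rows[rows$coefficient < 0, ]
    prod <- rows[rows$coefficient > 0, ]
    if (nrow(reac)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (j in seq_len(nrow(reac))) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = reac$metabolite[j],
                            stoichiometry = num(-reac$coefficient[j]),
                            constant = "true")
      }
    }
    if (nrow(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (j in seq_len(nrow(prod))) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = prod$metabolite[j],
                            stoichiometry = num(prod$coefficient[j]),
                            constant = "true")
      }
    }
  }

  obj <- model$reactions[model$reactions$objective != 0, ]
  if (nrow(obj)) {
    ol <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj1")
    on <- xml2::xml_add_child(ol, "fbc:objective", "fbc:id" = "obj1",
                              "fbc:type" = "maximize")
    fl <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
    for (i in seq_len(nrow(obj))) {
      xml2::xml_add_child(fl, "fbc:fluxObjective",
                          "fbc:reaction" = obj$id[i],
                          "fbc:coefficient" = num(obj$objective[i]))
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}
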