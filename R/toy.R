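# Parametric toy cross-feeding communities with closed-form balanced-growth
# optima. A producer ferments substrate S to a cross-fed metabolite X (and
# ATP); one or two consumers oxidize X to a final product P. ATP is modeled
# explicitly (1 ATP per mmol substrate) so that the non-growth-associated
# maintenance demand -- a lower bound on ATP hydrolysis, scaled by the
# species fraction -- couples yields to the growth rate exactly as
#   Y(mu) = mu * Y0 / (mu + m * Y0),
# where Y0 is the stoichiometric yield (gDW biomass per mmol ATP-bearing
# substrate) and m the maintenance coefficient (mmol ATP/gDW/h). When a
# species' waste pathway is off, the ATP-hydrolysis upper bound is pinned to
# the maintenance value and the balanced composition is unique; switching
# waste on lets the species burn surplus ATP (equivalent to converting
# substrate to the cross-fed metabolite with zero biomass gain), which
# widens the feasible composition range and creates the OptDeg < 1 region.

#' Parameters of a two-species toy cross-feeding community
#'
#' @param yield_a,yield_b Stoichiometric biomass yields Y0 of producer and
#'   consumer (gDW/mmol of their substrate).
#' @param cross_stoich mmol of cross-fed metabolite X produced per mmol of
#'   substrate S catabolized by the producer.
#' @param cap_a Producer substrate-uptake cap (mmol/gDW_A/h).
#' @param cap_b Consumer X-uptake cap (mmol/gDW_B/h).
#' @param maint_a,maint_b ATP maintenance coefficients (mmol ATP/gDW/h).
#' @param waste_a,waste_b Allow the species to burn ATP beyond maintenance
#'   (energy spilling / substrate wasting).
#' @return A `toy_spec` list.
#' @export
toy_pair_spec <- function(yield_a = 0.05, yield_b = 0.02, cross_stoich = 1,
                          cap_a = 10, cap_b = 15, maint_a = 0, maint_b = 0,
                          waste_a = FALSE, waste_b = FALSE) {
  stopifnot(yield_a > 0, yield_b > 0, cross_stoich > 0, cap_a > 0, cap_b > 0,
            maint_a >= 0, maint_b >= 0)
  structure(list(yield_a = yield_a, yield_b = yield_b,
                 cross_stoich = cross_stoich, cap_a = cap_a, cap_b = cap_b,
                 maint_a = maint_a, maint_b = maint_b,
                 waste_a = waste_a, waste_b = waste_b),
            class = "toy_spec")
}

# One toy species: uptake, catabolism (substrate -> ATP + x product),
# product export, biomass synthesis from ATP, ATP maintenance.
toy_species_model <- function(substrate, product, yield0, x, cap, maint,
                              waste) {
  mets <- tibble::tibble(
    id = c(substrate, paste0(substrate, "_c"), "ATP",
           paste0(product, "_c"), product, "BM"),
    compartment = c("env", "c", "c", "c", "env", "env"),
    boundary = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  rxns <- tibble::tibble(
    id = c("upt", "cat", "exp", "bio", "maint"),
    lb = c(0, 0, 0, 0, maint),
    ub = c(cap, DEFAULT_UB, DEFAULT_UB, DEFAULT_UB,
           if (waste) DEFAULT_UB else maint),
    reversible = FALSE,
    objective = c(0, 0, 0, 1, 0))
  st <- tibble::tibble(
    reaction = c("upt", "upt",
                 "cat", "cat", "cat",
                 "exp", "exp",
                 "bio", "bio",
                 "maint"),
    metabolite = c(substrate, paste0(substrate, "_c"),
                   paste0(substrate, "_c"), "ATP", paste0(product, "_c"),
                   paste0(product, "_c"), product,
                   "ATP", "BM",
                   "ATP"),
    coefficient = c(-1, 1,
                    -1, 1, x,
                    -1, 1,
                    -1 / yield0, 1,
                    -1))
  stoich_model(mets, rxns, st)
}

toy_species_spec <- function(id, substrate, product, yield0, x, cap, maint,
                             waste) {
  model <- toy_species_model(substrate, product, yield0, x, cap, maint, waste)
  caps <- c(upt = cap)
  if (!waste) caps <- c(caps, maint = maint)
  species_spec(model, id, biomass_rxn = "bio", substrates = substrate,
               atp_maintenance = maint, maintenance_rxn = "maint",
               rate_caps = caps)
}

#' Build the two-species toy community
#'
#' @param spec A [toy_pair_spec()].
#' @return List with `species` (two [species_spec()]s, ids `"A"` and
#'   `"B"`), `policy` (S from the medium, X closed, P accumulating) and
#'   `template` (the assembled [community_model]).
#' @export
make_toy_pair <- function(spec = toy_pair_spec()) {
  a <- toy_species_spec("A", "S", "X", spec$yield_a, spec$cross_stoich,
                        spec$cap_a, spec$maint_a, spec$waste_a)
  b <- toy_species_spec("B", "X", "P", spec$yield_b, 1, spec$cap_b,
                        spec$maint_b, spec$waste_b)
  policy <- exchange_policy(closed = "X", accumulating = "P", medium = "S")
  list(species = list(a, b), policy = policy,
       template = assemble_community(list(a, b), policy))
}

#' Build a three-species toy community (one producer, two X consumers)
#'
#' The two consumers compete for the cross-fed metabolite; with identical
#' parameters they are functionally interchangeable and the optimal
#' composition is a line segment rather than a point.
#'
#' @param spec A [toy_pair_spec()]; the consumer parameters are reused for
#'   both consumers unless `yield_c`/`cap_c`/`maint_c`/`waste_c` are given.
#' @param yield_c,cap_c,maint_c,waste_c Optional overrides for the second
#'   consumer.
#' @param product_c Product metabolite of the second consumer; giving it a
#'   distinct name makes the flux split between the consumers visible in
#'   product rates and yields.
#' @return As [make_toy_pair()], with species ids `"A"`, `"B"`, `"C"`.
#' @export
make_toy_trio <- function(spec = toy_pair_spec(), yield_c = spec$yield_b,
                          cap_c = spec$cap_b, maint_c = spec$maint_b,
                          waste_c = spec$waste_b, product_c = "P") {
  a <- toy_species_spec("A", "S", "X", spec$yield_a, spec$cross_stoich,
                        spec$cap_a, spec$maint_a, spec$waste_a)
  b <- toy_species_spec("B", "X", "P", spec$yield_b, 1, spec$cap_b,
                        spec$maint_b, spec$waste_b)
  cc <- toy_species_spec("C", "X", product_c, yield_c, 1, cap_c, maint_c,
                         waste_c)
  policy <- exchange_policy(closed = "X",
                            accumulating = unique(c("P", product_c)),
                            medium = "S")
  list(species = list(a, b, cc), policy = policy,
       template = assemble_community(list(a, b, cc), policy))
}

#' Closed-form balanced-growth optimum of the toy pair
#'
#' Independent of the LP machinery. The apparent yields at growth rate `mu`
#' are `Y_i(mu) = mu Y0_i / (mu + m_i Y0_i)`; balanced growth with a closed
#' X pool forces `F_A / F_B = Y_A(mu) / (x Y_B(mu))`, and the uptake caps
#' bound the achievable growth rate by
#' `mu_max = min(Y0_A (cap_A - m_A), Y0_B (cap_B - m_B))`.
#'
#' @param spec A [toy_pair_spec()].
#' @param mu Growth rate at which to evaluate the balanced composition;
#'   defaults to the maximum.
#' @return List `mu_max`, `f_star` (named composition at `mu`), `yields`
#'   (apparent yields at `mu`).
#' @export
oracle_balanced_optimum <- function(spec = toy_pair_spec(), mu = NULL) {
  mu_max <- min(spec$yield_a * (spec$cap_a - spec$maint_a),
                spec$yield_b * (spec$cap_b - spec$maint_b))
  if (mu_max <= 0) stop("maintenance exceeds capacity; no growth possible")
  if (is.null(mu)) mu <- mu_max
  ya <- mu * spec$yield_a / (mu + spec$maint_a * spec$yield_a)
  yb <- mu * spec$yield_b / (mu + spec$maint_b * spec$yield_b)
  fa <- ya / (ya + spec$cross_stoich * yb)
  list(mu_max = mu_max, f_star = c(A = fa, B = 1 - fa),
       yields = c(A = ya, B = yb))
}

#' Sample random toy-pair parameters
#'
#' Log-uniform draws spanning one order of magnitude per parameter, for
#' property-style tests. Waste pathways are enabled so that off-optimum
#' compositions remain feasible.
#'
#' @param n Number of specs.
#' @param seed RNG seed (default 0 for reproducible suites).
#' @param maintenance Include nonzero maintenance coefficients with
#'   probability 1/2.
#' @return List of `toy_spec`s.
#' @export
sample_toy_specs <- function(n, seed = 0, maintenance = TRUE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m_a <- if (maintenance && stats::runif(1) < 0.5)
      10^stats::runif(1, -1, 0) else 0
    m_b <- if (maintenance && stats::runif(1) < 0.5)
      10^stats::runif(1, -1, 0) else 0
    toy_pair_spec(
      yield_a = 10^stats::runif(1, -2, -1),
      yield_b = 10^stats::runif(1, -2, -1),
      cross_stoich = 10^stats::runif(1, -0.5, 0.5),
      cap_a = 10^stats::runif(1, 0.5, 1.5),
      cap_b = 10^stats::runif(1, 0.5, 1.5),
      maint_a = m_a, maint_b = m_b,
      waste_a = TRUE, waste_b = TRUE)
  })
}

#' Export the toy species models as SBML files
#'
#' Convenience for driving the command-line interface without any external
#' model files.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [toy_pair_spec()].
#' @return Named character vector of written paths.
#' @export
export_toy_models <- function(dir, spec = toy_pair_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pair <- make_toy_pair(spec)
  paths <- c(A = file.path(dir, "toy_producer.xml"),
             B = file.path(dir, "toy_consumer.xml"))
  write_sbml(pair$species[[1]]$model, paths[["A"]], id = "toy_producer")
  write_sbml(pair$species[[2]]$model, paths[["B"]], id = "toy_consumer")
  paths
}
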