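# Core stoichiometric model: construction, validation, FBA contract,
# flux extrema and maximum yields.

chain_model <- function(uptake_cap = 10, yield = 0.05) {
  # uptake S -> A, biomass (1/yield) A -> BM
  stoich_model(
    metabolites = tibble::tibble(id = c("S", "A", "BM"),
                                 boundary = c(TRUE, FALSE, TRUE)),
    reactions = tibble::tibble(id = c("upt", "bio"), lb = 0,
                               ub = c(uptake_cap, 1000),
                               objective = c(0, 1)),
    stoichiometry = tibble::tibble(
      reaction = c("upt", "upt", "bio", "bio"),
      metabolite = c("S", "A", "A", "BM"),
      coefficient = c(-1, 1, -1 / yield, 1)))
}

test_that("model validation rejects inconsistent input", {
  mets <- tibble::tibble(id = c("A", "A"))
  expect_error(stoich_model(mets, tibble::tibble(id = "r"),
                            tibble::tibble(reaction = "r", metabolite = "A",
                                           coefficient = 1)),
               "duplicate metabolite")
  expect_error(stoich_model(tibble::tibble(id = "A"),
                            tibble::tibble(id = "r"),
                            tibble::tibble(reaction = "r", metabolite = "B",
                                           coefficient = 1)),
               "unknown metabolites")
  expect_error(stoich_model(tibble::tibble(id = "A"),
                            tibble::tibble(id = "r", lb = 2, ub = 1),
                            tibble::tibble(reaction = "r", metabolite = "A",
                                           coefficient = 1)),
               "lb > ub")
  expect_error(stoich_model(tibble::tibble(id = "A"),
                            tibble::tibble(id = "r", lb = -1, ub = 1,
                                           reversible = FALSE),
                            tibble::tibble(reaction = "r", metabolite = "A",
                                           coefficient = 1)),
               "irreversible")
})

test_that("stoichiometric matrix covers internal metabolites only", {
  m <- chain_model()
  N <- stoich_matrix(m)
  expect_equal(rownames(N), "A")
  expect_equal(N["A", ], c(upt = 1, bio = -20))
  Nb <- stoich_matrix(m, boundary = TRUE)
  expect_equal(nrow(Nb), 3)
})

test_that("forced single-pathway FBA gives the stoichiometric optimum", {
  m <- chain_model(uptake_cap = 10, yield = 0.05)
  sol <- fba(m)
  expect_equal(attr(sol, "status"), "optimal")
  expect_equal(attr(sol, "objective_value"), 0.5, tolerance = 1e-9)
  # steady state and bounds on the returned distribution
  N <- stoich_matrix(m)
  r <- sol$flux
  expect_lt(max(abs(N %*% r)), 1e-6)
  expect_true(all(r >= m$reactions$lb - 1e-9))
  expect_true(all(r <= m$reactions$ub + 1e-9))
})

test_that("fba optimum is invariant to reaction order", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_net_lp(n_rxn = 6, n_met = 3)
    m1 <- stoich_model(
      tibble::tibble(id = paste0("M", 1:3)),
      tibble::tibble(id = paste0("R", 1:6), lb = p$lb, ub = p$ub,
                     objective = abs(p$obj)),
      tidyr::crossing(reaction = paste0("R", 1:6),
                      metabolite = paste0("M", 1:3)) |>
        dplyr::mutate(coefficient = as.vector(p$A)) |>
        dplyr::filter(coefficient != 0))
    perm <- sample(6)
    m2 <- m1
    m2$reactions <- m2$reactions[perm, ]
    v1 <- attr(fba(m1), "objective_value")
    v2 <- attr(fba(m2), "objective_value")
    expect_equal(v1, v2, tolerance = 1e-9)
  }
})

test_that("fba on small random networks equals brute-force enumeration", {
  set.seed(3)
  for (i in 1:10) {
    p <- random_net_lp(n_rxn = sample(5:8, 1), n_met = 3)
    res <- solve_lp(p$obj, p$A, p$b, p$lb, p$ub, "max")
    oracle <- brute_lp(p$obj, p$A, p$b, p$lb, p$ub, "max")
    expect_equal(res$objval, oracle, tolerance = 1e-7)
  }
})

test_that("flux extremum honors fixed fluxes and blocked reactions", {
  m <- chain_model(uptake_cap = 10, yield = 0.05)
  # biomass fixed at max: uptake must be exactly the stoichiometric demand
  ext <- flux_extremum(m, "upt", fixed = c(bio = 0.5), sense = "min")
  expect_equal(ext$status, "optimal")
  expect_equal(ext$value, 10, tolerance = 1e-9)
  # a blocked reaction has maximum zero
  m2 <- set_bounds(m, "upt", ub = 0)
  ext2 <- flux_extremum(m2, "bio", sense = "max")
  expect_equal(ext2$value, 0, tolerance = 1e-12)
  # fixing an unreachable flux is reported infeasible
  ext3 <- flux_extremum(m, "upt", fixed = c(bio = 2), sense = "min")
  expect_equal(ext3$status, "infeasible")
})

test_that("maximum yield is the stoichiometric yield on a single pathway", {
  m <- chain_model(yield = 0.02)
  expect_equal(max_yield(m, "bio", "upt"), 0.02, tolerance = 1e-9)
  # with zero maintenance, fixed-growth apparent yield equals the true one
  expect_equal(max_yield(m, "bio", "upt", fixed_growth = 0.1), 0.02,
               tolerance = 1e-9)
})

test_that("maintenance makes the apparent yield growth-rate dependent", {
  spec <- make_toy_pair(toy_pair_spec(maint_a = 2))$species[[1]]
  m <- single_species_model(spec)
  upt <- "upt"
  y0 <- 0.05
  mm <- 2
  for (mu in c(0.05, 0.1, 0.2, 0.4)) {
    expect_equal(max_yield(m, "bio", upt, fixed_growth = mu),
                 mu * y0 / (mu + mm * y0), tolerance = 1e-8)
  }
  # the true yield strips the maintenance demand
  expect_equal(max_yield(m, "bio", upt, maintenance_rxn = "maint"), y0,
               tolerance = 1e-9)
})

test_that("a substrate that cannot support growth is flagged", {
  m <- chain_model()
  m <- set_bounds(m, "upt", ub = 0)
  y <- max_yield(m, "bio", "upt")
  expect_true(is.na(y))
  expect_match(attr(y, "message"), "does not support growth")
})
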