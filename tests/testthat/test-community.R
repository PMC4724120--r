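# Community assembly: namespacing, exchange pool, composition scaling,
# and the balanced-growth identity.

test_that("two species sharing a metabolite assemble around a pool", {
  pair <- make_toy_pair()
  tpl <- pair$template
  m <- tpl$model
  expect_true("X_pool" %in% m$metabolites$id)
  expect_false(m$metabolites$boundary[m$metabolites$id == "X_pool"])
  # one export (producer) and one uptake (consumer) transport touch it
  expect_setequal(reactions_touching(m, "X_pool", "out"), "exp_A")
  expect_setequal(reactions_touching(m, "X_pool", "in"), "upt_B")
  # community biomass reaction consumes both species biomasses
  st <- m$stoichiometry
  bm <- st[st$reaction == "BM_community", ]
  expect_setequal(bm$metabolite, c("BM_A", "BM_B", "BM_community"))
  # internal metabolite names are disjoint across species
  expect_true(all(grepl("_(A|B|pool)$|^BM_", m$metabolites$id)))
  # closed pool metabolite has no environment reaction
  expect_false(any(grepl("^ENV_(upt|exp)_X$", m$reactions$id)))
  # medium and accumulating metabolites do
  expect_true("ENV_upt_S" %in% m$reactions$id)
  expect_true("ENV_exp_P" %in% m$reactions$id)
})

test_that("declaring a substrate with no transport is an assembly error", {
  pair <- make_toy_pair()
  bad <- pair$species[[1]]
  bad$substrates <- c("S", "P")   # producer has no uptake transport for P
  expect_error(assemble_community(list(bad, pair$species[[2]]),
                                  pair$policy),
               "no transport")
})

test_that("instantiation scales species-specific bounds by the fraction", {
  tpl <- make_toy_pair(toy_pair_spec(maint_a = 4.3))$template
  m <- instantiate_community(tpl, c(A = 0.3, B = 0.7))
  rx <- m$reactions
  # producer uptake cap 10 per gDW_A at F_A = 0.3 -> 3 per gDW_C
  expect_equal(rx$ub[rx$id == "upt_A"], 3, tolerance = 1e-12)
  # maintenance lower bound 4.3 * 0.3 = 1.29
  expect_equal(rx$lb[rx$id == "maint_A"], 1.29, tolerance = 1e-12)
  # generic bounds are left unscaled
  expect_equal(rx$ub[rx$id == "cat_A"], 1000)
  # community biomass stoichiometry carries F
  st <- m$stoichiometry
  expect_equal(st$coefficient[st$reaction == "BM_community" &
                                st$metabolite == "BM_A"], -0.3)
})

test_that("compositions off the simplex are rejected", {
  tpl <- make_toy_pair()$template
  expect_error(instantiate_community(tpl, c(A = 0.6, B = 0.6)), "sum to 1")
  expect_error(instantiate_community(tpl, c(A = -0.2, B = 1.2)), "0, 1")
})

test_that("a species at fraction zero is shut off entirely", {
  pair <- make_toy_pair()
  m <- instantiate_community(pair$template, c(A = 1, B = 0))
  rx <- m$reactions
  b_rxns <- pair$template$species_reactions$reaction[
    pair$template$species_reactions$species == "B"]
  expect_true(all(rx$ub[rx$id %in% b_rxns] == 0))
  # the consumer is essential (closed X pool): community cannot grow
  g <- max_community_growth(pair$template, c(A = 1, B = 0))
  expect_true(g$feasible)
  expect_equal(g$mu_c_opt, 0, tolerance = 1e-9)
})

test_that("balanced growth forces r_BMi = F_i * mu_C on optimal fluxes", {
  tpl <- make_toy_pair(toy_pair_spec(waste_a = TRUE, waste_b = TRUE))$template
  for (fa in c(0.3, 0.5, 5 / 7)) {
    fr <- c(A = fa, B = 1 - fa)
    m <- instantiate_community(tpl, fr)
    sol <- fba(m, "BM_community")
    mu <- attr(sol, "objective_value")
    r_bma <- sol$flux[sol$reaction == "bio_A"]
    r_bmb <- sol$flux[sol$reaction == "bio_B"]
    expect_equal(r_bma, fa * mu, tolerance = 1e-8)
    expect_equal(r_bmb, (1 - fa) * mu, tolerance = 1e-8)
  }
})

test_that("closed pool metabolites have zero net environment exchange", {
  tpl <- make_toy_pair(toy_pair_spec(waste_a = TRUE, waste_b = TRUE))$template
  m <- instantiate_community(tpl, c(A = 0.5, B = 0.5))
  sol <- fba(m, "BM_community")
  # X_pool is balanced: production equals consumption within the community
  N <- stoich_matrix(m)
  expect_lt(abs(sum(N["X_pool", ] * sol$flux)), 1e-8)
})

test_that("single-species community reproduces the single-species FBA", {
  spec <- make_toy_pair()$species[[1]]   # producer alone, X accumulating
  policy <- exchange_policy(medium = "S", accumulating = "X")
  tpl <- assemble_community(list(spec), policy)
  g <- max_community_growth(tpl, c(A = 1))
  single <- fba(single_species_model(spec), "bio")
  expect_equal(g$mu_c_opt, attr(single, "objective_value"),
               tolerance = 1e-9)
  res <- optimality_degree(tpl, c(A = 1))
  expect_equal(res$optdeg, 1, tolerance = 1e-9)
})

test_that("reversible pool transports are split into irreversible halves", {
  # author a species whose X transport is reversible; assembly must split
  m <- stoich_model(
    metabolites = tibble::tibble(id = c("S", "S_c", "X", "BM"),
                                 boundary = c(TRUE, FALSE, TRUE, TRUE)),
    reactions = tibble::tibble(id = c("upt", "tx", "bio"),
                               lb = c(0, -50, 0), ub = c(10, 50, 1000),
                               objective = c(0, 0, 1)),
    stoichiometry = tibble::tibble(
      reaction = c("upt", "upt", "tx", "tx", "bio", "bio"),
      metabolite = c("S", "S_c", "S_c", "X", "S_c", "BM"),
      coefficient = c(-1, 1, -1, 1, -20, 1)))
  spec <- species_spec(m, "Z", "bio", substrates = "S")
  tpl <- assemble_community(list(spec),
                            exchange_policy(medium = "S",
                                            accumulating = "X"))
  rx <- tpl$model$reactions
  # X-pool transport split into export and (reverse) uptake halves
  expect_true(all(c("tx_Z", "tx_Z_rev") %in% rx$id))
  expect_true(all(rx$lb[rx$id %in% c("tx_Z", "tx_Z_rev")] == 0))
  expect_equal(rx$ub[rx$id == "tx_Z_rev"], 50)
})
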