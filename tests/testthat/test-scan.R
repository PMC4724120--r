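# Composition scanning: lattice construction, landscape shape, extremal
# product rates and yields, optimum location, export.

test_that("simplex lattice has the right size and content", {
  expect_equal(nrow(simplex_grid(2, 0.01)), 101)
  expect_equal(nrow(simplex_grid(3, 0.01)), 5151)   # C(102, 2)
  g <- simplex_grid(2, 0.5)
  expect_equal(as.matrix(g)[order(g$F1), ],
               matrix(c(0, 0.5, 1, 1, 0.5, 0), 3, 2,
                      dimnames = list(NULL, c("F1", "F2"))))
  expect_true(all(abs(rowSums(simplex_grid(3, 0.1)) - 1) < 1e-12))
})

toy_scan <- function(step = 0.05) {
  pw <- make_toy_pair(toy_pair_spec(waste_a = TRUE, waste_b = TRUE))
  scan_compositions(pw$template, step = step, product = "P",
                    reference_substrate = "S")
}

test_that("the max-growth scan shows a plateau and the yield-optimal point", {
  sc <- toy_scan(step = 0.05)
  expect_equal(nrow(sc), 21)
  # plateau: the maximum growth rate is attained on an interval
  mu_max <- max(sc$mu_c_max, na.rm = TRUE)
  expect_equal(mu_max, 0.3, tolerance = 1e-6)
  at_max <- which(sc$mu_c_max > mu_max - 1e-9)
  expect_gt(length(at_max), 1)
  expect_equal(at_max, seq(min(at_max), max(at_max)))  # contiguous interval
  # OptDeg peaks within one lattice step of the closed-form optimum 5/7
  best <- sc$F_A[which.max(sc$optdeg)]
  expect_lt(abs(best - 5 / 7), 0.05 + 1e-12)
})

test_that("infeasible cells are flagged, never dropped", {
  pair <- make_toy_pair()          # no waste: off-balance F cannot grow
  sc <- scan_compositions(pair$template, step = 0.25,
                          mu_c = c(0.1, 0.4))
  expect_equal(nrow(sc), 10)       # 5 compositions x 2 rates, all present
  expect_true(any(!sc$feasible))
  expect_true(all(is.na(sc$optdeg[!sc$feasible])))
  # mu above the simplex-wide maximum is infeasible everywhere
  expect_true(all(!sc$feasible[sc$mu_c == 0.4]))
})

test_that("scan rows are order-independent", {
  pw <- make_toy_pair(toy_pair_spec(waste_a = TRUE, waste_b = TRUE))
  grid <- simplex_grid(2, 0.2)
  sc1 <- scan_compositions(pw$template, compositions = grid)
  sc2 <- scan_compositions(pw$template,
                           compositions = grid[rev(seq_len(nrow(grid))), ])
  key <- function(x) dplyr::arrange(tibble::as_tibble(x), .data$F_A)
  expect_equal(key(sc1), key(sc2), tolerance = 1e-12)
})

test_that("minimum product rate is tight, zero at rest, monotone in rate", {
  pair <- make_toy_pair()          # fully determined at the balance point
  fr <- c(A = 5 / 7, B = 2 / 7)
  lo <- min_product_rate(pair$template, fr, 0.3, "P", sense = "min")
  hi <- min_product_rate(pair$template, fr, 0.3, "P", sense = "max")
  expect_equal(lo$value, hi$value, tolerance = 1e-8)
  expect_equal(lo$value, 30 / 7, tolerance = 1e-6)   # 1 P per X per S
  # zero growth, zero maintenance: nothing needs to run
  z <- min_product_rate(pair$template, fr, 0, "P")
  expect_equal(z$value, 0, tolerance = 1e-9)
  # monotone nondecreasing in the growth rate at fixed composition
  pw <- make_toy_pair(toy_pair_spec(waste_a = TRUE, waste_b = TRUE,
                                    maint_a = 0.5, maint_b = 0.5))
  rates <- vapply(c(0.05, 0.1, 0.15, 0.2), function(mu) {
    min_product_rate(pw$template, c(A = 0.6, B = 0.4), mu, "P")$value
  }, numeric(1))
  expect_true(all(diff(rates) > -1e-9))
})

test_that("product rate minimum bounds every feasible product flux", {
  pw <- make_toy_pair(toy_pair_spec(waste_a = TRUE, waste_b = TRUE))
  fr <- c(A = 0.6, B = 0.4)
  mu <- 0.15
  lo <- min_product_rate(pw$template, fr, mu, "P")$value
  # sample feasible points by optimizing random directions
  m <- instantiate_community(pw$template, fr)
  m <- set_bounds(m, "BM_community", lb = mu, ub = mu)
  set.seed(5)
  for (i in 1:5) {
    obj <- stats::setNames(stats::rnorm(3),
                           sample(m$reactions$id, 3))
    sol <- fba(m, obj, sense = "max")
    p_flux <- sol$flux[sol$reaction == "ENV_exp_P"]
    expect_gte(p_flux, lo - 1e-8)
  }
})

test_that("toy product yield equals the stoichiometric ratio", {
  pw <- make_toy_pair(toy_pair_spec(waste_a = TRUE, waste_b = TRUE))
  y <- min_product_yield(pw$template, c(A = 0.6, B = 0.4), 0.15, "P", "S")
  expect_equal(y$status, "optimal")
  expect_equal(y$yield, 1, tolerance = 1e-8)   # 1 X per S, 1 P per X
})

test_that("Charnes-Cooper and bisection yields agree", {
  # two consumers with distinct products: the P/S yield varies with the
  # allocation of cross-fed X, so the minimum is a nontrivial LP
  trio <- make_toy_trio(toy_pair_spec(waste_a = TRUE, waste_b = TRUE),
                        product_c = "Q", waste_c = TRUE)
  fr <- c(A = 0.5, B = 0.3, C = 0.2)
  mu <- 0.1
  cc <- min_product_yield(trio$template, fr, mu, "P", "S",
                          method = "charnes_cooper")
  bi <- min_product_yield(trio$template, fr, mu, "P", "S",
                          method = "bisection", tol = 1e-8)
  expect_equal(cc$status, "optimal")
  expect_equal(cc$yield, bi$yield, tolerance = 1e-6)
  # and the minimum is strictly below the maximum (real freedom)
  mx <- min_product_yield(trio$template, fr, mu, "P", "S", sense = "max")
  expect_gt(mx$yield, cc$yield + 1e-3)
})

test_that("zero reference uptake marks the yield undefined", {
  # no waste, no maintenance, zero growth: the only feasible flux is zero,
  # so the reference uptake vanishes over the whole feasible set
  pair <- make_toy_pair()
  y <- min_product_yield(pair$template, c(A = 5 / 7, B = 2 / 7), 0, "P", "S")
  expect_equal(y$status, "undefined")
  expect_true(is.na(y$yield))
})

test_that("competition between equivalent consumers yields a line of optima", {
  # Y_A = 0.06, Y_B = Y_C = 0.04: balanced producer fraction is 0.6,
  # any split of the remaining 0.4 between the two consumers is optimal
  sp <- toy_pair_spec(yield_a = 0.06, yield_b = 0.04, cap_a = 10,
                      cap_b = 15, waste_a = TRUE, waste_b = TRUE)
  trio <- make_toy_trio(sp, waste_c = TRUE)
  sc <- scan_compositions(trio$template, step = 0.1)
  opt <- locate_optima(sc, tol = 1e-6)
  expect_gt(nrow(opt), 2)                      # a set, not a point
  expect_equal(unique(round(opt$F_A, 9)), 0.6)
  expect_equal(sort(opt$F_B), seq(0, 0.4, by = 0.1), tolerance = 1e-9)
})

test_that("scan grids export to CSV and JSON faithfully", {
  sc <- toy_scan(step = 0.25)
  fcsv <- withr::local_tempfile(fileext = ".csv")
  fjson <- withr::local_tempfile(fileext = ".json")
  write_scan(sc, fcsv)
  write_scan(sc, fjson)
  back <- readr::read_csv(fcsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sc))
  expect_equal(back$optdeg, signif(sc$optdeg, 6), tolerance = 1e-12)
  j <- jsonlite::read_json(fjson, simplifyVector = TRUE)
  expect_equal(nrow(j), nrow(sc))
  # long format carries one row per species per cell
  lg <- scan_long(sc)
  expect_equal(nrow(lg), 2 * nrow(sc))
})

test_that("the growth-rate axis spans zero to the simplex-wide maximum", {
  pw <- make_toy_pair(toy_pair_spec(waste_a = TRUE, waste_b = TRUE))
  ax <- mu_axis(pw$template, n = 11, step = 0.1)
  expect_equal(length(ax), 11)
  expect_equal(ax[1], 0)
  expect_equal(max(ax), 0.3, tolerance = 1e-6)
})
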