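# Composition-simplex and growth-rate scanning: feasibility, maximum
# community growth rate, optimality degree, and extremal product rates and
# yields per lattice point. Minimum product yields are linear-fractional
# programs solved exactly by the Charnes-Cooper transformation (a bisection
# solver is provided as an independent alternative).

#' Lattice of community compositions on the simplex
#'
#' All composition vectors with entries on the `step` lattice summing to
#' one. For two species and step 0.01 this gives 101 compositions, for
#' three species 5151.
#'
#' @param n_species Number of species.
#' @param step Lattice step; `1/step` must be (numerically) an integer.
#' @return A tibble with columns `F1` ... `Fn`, one row per composition.
#' @export
simplex_grid <- function(n_species, step = 0.01) {
  k <- 1 / step
  if (abs(k - round(k)) > 1e-9) stop("step must divide 1")
  k <- as.integer(round(k))
  rec <- function(n, total) {
    if (n == 1L) return(matrix(total, 1L, 1L))
    out <- lapply(0:total, function(i) cbind(i, rec(n - 1L, total - i)))
    do.call(rbind, out)
  }
  m <- rec(n_species, k) / k
  colnames(m) <- paste0("F", seq_len(n_species))
  tibble::as_tibble(m)
}

# yield tables are growth-rate dependent (through maintenance) but
# composition independent; cache them per scan keyed by rounded mu
yield_cache <- function(template) {
  cache <- new.env(parent = emptyenv())
  function(mu) {
    key <- sprintf("%.9f", mu)
    if (is.null(cache[[key]])) cache[[key]] <- yield_table(template, mu)
    cache[[key]]
  }
}

#' Scan the composition simplex
#'
#' Evaluates every composition of the lattice (or a supplied set) at the
#' maximum community growth rate (`mu_c = "max"`) or at each of a vector of
#' fixed growth rates. Infeasible points are kept with an explicit
#' `feasible = FALSE` flag and `NA` metrics, never dropped. When `product`
#' is given, the minimal product export rate (and, with
#' `reference_substrate`, the minimal product yield) is computed per point.
#'
#' @param template A [assemble_community()] template.
#' @param step Lattice step for [simplex_grid()].
#' @param compositions Optional tibble of compositions (columns matching
#'   the species count) overriding the lattice.
#' @param mu_c `"max"`, or a numeric vector of community growth rates.
#' @param product Optional pool metabolite id (e.g., `"CH4"`) for minimum
#'   production-rate/yield columns.
#' @param reference_substrate Optional pool metabolite id the product yield
#'   refers to (e.g., the primary carbon source).
#' @return A `commfba_scan` tibble: one row per (composition, growth rate)
#'   with columns `F_<species>`, `mu_c`, `mu_c_max`, `feasible`, `z_opt`,
#'   `optdeg` and optionally `min_product_rate`, `min_product_yield`.
#' @export
scan_compositions <- function(template, step = 0.01, compositions = NULL,
                              mu_c = "max", product = NULL,
                              reference_substrate = NULL) {
  sp <- template$species$species
  n <- length(sp)
  if (is.null(compositions)) compositions <- simplex_grid(n, step)
  stopifnot(ncol(compositions) == n)
  yields_at <- yield_cache(template)

  eval_point <- function(fr, mu, mu_max) {
    row <- tibble::as_tibble(as.list(stats::setNames(fr, paste0("F_", sp))))
    row$mu_c <- mu
    row$mu_c_max <- mu_max
    feas <- !is.na(mu_max) && !is.na(mu) && mu <= mu_max + 1e-9
    if (feas && mu > 1e-9) {
      z <- min_weighted_substrate(template, fr, mu, yields_at(mu))
      if (z$status == "optimal") {
        row$z_opt <- z$z_opt
        row$optdeg <- mu / z$z_opt
      } else {
        feas <- FALSE
        row$z_opt <- NA_real_
        row$optdeg <- NA_real_
      }
    } else {
      row$z_opt <- NA_real_
      row$optdeg <- NA_real_
    }
    row$feasible <- feas
    if (!is.null(product)) {
      if (feas) {
        pr <- min_product_rate(template, fr, mu, product)
        row$min_product_rate <- if (pr$status == "optimal") pr$value else
          NA_real_
        if (!is.null(reference_substrate)) {
          py <- min_product_yield(template, fr, mu, product,
                                  reference_substrate)
          row$min_product_yield <- py$yield
        }
      } else {
        row$min_product_rate <- NA_real_
        if (!is.null(reference_substrate)) row$min_product_yield <- NA_real_
      }
    }
    row
  }

  rows <- vector("list", 0L)
  for (i in seq_len(nrow(compositions))) {
    fr <- stats::setNames(as.numeric(compositions[i, ]), sp)
    g <- max_community_growth(template, fr)
    mu_max <- g$mu_c_opt
    if (identical(mu_c, "max")) {
      rows[[length(rows) + 1L]] <- eval_point(fr, mu_max, mu_max)
    } else {
      for (mu in mu_c) {
        rows[[length(rows) + 1L]] <- eval_point(fr, mu, mu_max)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, species = sp,
            class = c("commfba_scan", class(out)))
}

#' Default growth-rate axis for fixed-rate scans
#'
#' Evenly spaced rates from 0 to the simplex-wide maximum community growth
#' rate.
#'
#' @param template A community template.
#' @param n Number of rates.
#' @param step Composition lattice step used to locate the maximum.
#' @return Numeric vector of growth rates.
#' @export
mu_axis <- function(template, n = 40, step = 0.05) {
  grid <- simplex_grid(nrow(template$species), step)
  sp <- template$species$species
  mu_max <- 0
  for (i in seq_len(nrow(grid))) {
    g <- max_community_growth(template,
                              stats::setNames(as.numeric(grid[i, ]), sp))
    if (isTRUE(g$feasible) && !is.na(g$mu_c_opt)) {
      mu_max <- max(mu_max, g$mu_c_opt)
    }
  }
  seq(0, mu_max, length.out = n)
}

# net environment export of a pool metabolite as objective coefficients
product_export_coefs <- function(model, product) {
  coef <- stats::setNames(numeric(0), character(0))
  exp_id <- paste0("ENV_exp_", product)
  upt_id <- paste0("ENV_upt_", product)
  if (exp_id %in% model$reactions$id) coef[exp_id] <- 1
  if (upt_id %in% model$reactions$id) coef[upt_id] <- -1
  if (!length(coef)) {
    stop("product '", product, "' has no environment link; it must have ",
         "an 'accumulating' (or 'medium') policy")
  }
  coef
}

#' Minimum product formation rate at a fixed operating point
#'
#' LP minimum of the product's net environment export at fixed composition
#' and community growth rate. With `at_z_opt = TRUE` the flux space is
#' additionally restricted to the yield-optimal face (secondary objective
#' pinned to its optimum).
#'
#' @param template A community template.
#' @param fractions Composition vector.
#' @param mu_c Community growth rate.
#' @param product Pool metabolite id.
#' @param sense `"min"` or `"max"`.
#' @param at_z_opt Restrict to z-optimal flux distributions.
#' @return One-row tibble `value`, `status`.
#' @export
min_product_rate <- function(template, fractions, mu_c, product,
                             sense = "min", at_z_opt = FALSE) {
  model <- instantiate_community(template, fractions)
  model <- set_bounds(model, template$community_rxn, lb = mu_c, ub = mu_c)
  coef <- objective_coefs(model, product_export_coefs(model, product))
  N <- stoich_matrix(model)
  A_leq <- NULL
  b_leq <- NULL
  if (at_z_opt) {
    z <- min_weighted_substrate(template, fractions, mu_c)
    if (z$status != "optimal") {
      return(tibble::tibble(value = NA_real_, status = z$status))
    }
    wt <- dplyr::inner_join(template$uptakes, yield_table(template, mu_c),
                            by = c("species", "substrate"))
    wt <- wt[!is.na(wt$yield), ]
    zc <- numeric(nrow(model$reactions))
    idx <- match(wt$reaction, model$reactions$id)
    zc[idx] <- zc[idx] + wt$yield
    A_leq <- matrix(zc, 1L)
    b_leq <- z$z_opt + 1e-9
  }
  res <- solve_lp(coef, N, rep(0, nrow(N)), model$reactions$lb,
                  model$reactions$ub, sense, A_leq = A_leq, b_leq = b_leq)
  tibble::tibble(value = res$objval, status = res$status)
}

# Charnes-Cooper: optimize p'r / q'r over {Nr=0, lb<=r<=ub} via y = t r,
# t >= 0, q'y = 1, N y = 0, lb t <= y <= ub t. Variables with lb < 0 are
# split into positive and negative parts so everything is nonnegative for
# the standard-form simplex.
cc_ratio_opt <- function(model, p, q, sense = c("min", "max")) {
  sense <- match.arg(sense)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  n <- length(lb)
  N <- stoich_matrix(model)
  neg <- which(lb < 0)
  nneg <- length(neg)
  # columns: y_plus (n), y_minus (nneg), t (1)
  expand <- function(v) c(v, -v[neg], 0)
  A_eq <- rbind(
    cbind(N, -N[, neg, drop = FALSE], 0),
    matrix(expand(q), 1L))
  b_eq <- c(rep(0, nrow(N)), 1)
  # y_j <= ub_j t  and  y_j >= lb_j t
  rows_ub <- cbind(diag(n), matrix(0, n, nneg), -ub)
  if (nneg) rows_ub[neg, n + seq_len(nneg)] <- -diag(nneg)
  sel_lb <- which(lb != 0)
  rows_lb <- cbind(-diag(n)[sel_lb, , drop = FALSE],
                   matrix(0, length(sel_lb), nneg),
                   lb[sel_lb])
  if (nneg) {
    rows_lb[, n + seq_len(nneg)] <-
      diag(n)[sel_lb, neg, drop = FALSE]
  }
  A_ineq <- rbind(rows_ub, rows_lb)
  b_ineq <- rep(0, nrow(A_ineq))
  n_slack <- nrow(A_ineq)
  ncols <- n + nneg + 1L
  A_std <- cbind(rbind(A_eq, A_ineq),
                 rbind(matrix(0, nrow(A_eq), n_slack), diag(n_slack)))
  b_std <- c(b_eq, b_ineq)
  pvec <- expand(p)
  c_std <- c(if (sense == "max") -pvec else pvec, numeric(n_slack))
  res <- simplex_core(c_std, A_std, b_std)
  if (res$status != "optimal") return(list(status = res$status))
  y <- res$x[seq_len(n)]
  if (nneg) y[neg] <- y[neg] - res$x[n + seq_len(nneg)]
  t <- res$x[ncols]
  list(status = "optimal", value = sum(p * y),
       r = if (t > 1e-12) y / t else rep(NA_real_, n))
}

#' Minimum (or maximum) product yield at a fixed operating point
#'
#' Extremum of product export divided by reference-substrate uptake over
#' the feasible flux space at fixed composition and growth rate -- a
#' linear-fractional program. The default solver is the exact
#' Charnes-Cooper transformation; `method = "bisection"` solves the same
#' problem by bisecting on the yield and testing feasibility, as an
#' independent check.
#'
#' @inheritParams min_product_rate
#' @param reference_substrate Pool metabolite id of the denominator
#'   (environment uptake).
#' @param method `"charnes_cooper"` or `"bisection"`.
#' @param tol Bisection termination tolerance on the yield.
#' @return One-row tibble `yield`, `status`; `status = "undefined"` when
#'   the reference uptake is zero over the whole feasible set.
#' @export
min_product_yield <- function(template, fractions, mu_c, product,
                              reference_substrate, sense = "min",
                              method = c("charnes_cooper", "bisection"),
                              tol = 1e-9) {
  method <- match.arg(method)
  model <- instantiate_community(template, fractions)
  model <- set_bounds(model, template$community_rxn, lb = mu_c, ub = mu_c)
  p <- objective_coefs(model, product_export_coefs(model, product))
  upt_id <- paste0("ENV_upt_", reference_substrate)
  if (!upt_id %in% model$reactions$id) {
    stop("reference substrate '", reference_substrate,
         "' has no environment uptake (policy 'medium' required)")
  }
  q <- objective_coefs(model, stats::setNames(1, upt_id))
  N <- stoich_matrix(model)

  # degenerate denominator: no feasible point consumes the reference
  qmax <- solve_lp(q, N, rep(0, nrow(N)), model$reactions$lb,
                   model$reactions$ub, "max")
  if (qmax$status != "optimal") {
    return(tibble::tibble(yield = NA_real_, status = qmax$status))
  }
  if (qmax$objval <= 1e-9) {
    return(tibble::tibble(yield = NA_real_, status = "undefined"))
  }

  if (method == "charnes_cooper") {
    res <- cc_ratio_opt(model, p, q, sense)
    if (res$status != "optimal") {
      return(tibble::tibble(yield = NA_real_, status = res$status))
    }
    return(tibble::tibble(yield = res$value, status = "optimal"))
  }

  # bisection on gamma: min-yield gamma* is the smallest gamma for which
  # some feasible r has p'r - gamma q'r <= 0 (max-yield: mirrored)
  check <- function(gamma) {
    d <- if (sense == "min") p - gamma * q else gamma * q - p
    res <- solve_lp(d, N, rep(0, nrow(N)), model$reactions$lb,
                    model$reactions$ub, "min")
    res$status == "optimal" && res$objval <= 1e-9
  }
  start <- fba(set_objective(model, template$community_rxn),
               template$community_rxn, "max")
  r0 <- start$flux
  g0 <- sum(p * r0) / max(sum(q * r0), 1e-12)
  lo <- 0
  hi <- max(g0 * 2, 1)
  while (!check(hi)) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (check(mid)) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  tibble::tibble(yield = hi, status = "optimal")
}

#' Compositions attaining the maximal optimality degree
#'
#' Filters a scan for rows with `OptDeg >= 1 - tol` (the predicted
#' operating points); in competition scenarios this is a set, not a single
#' point, so all qualifying rows are returned.
#'
#' @param scan A [scan_compositions()] result.
#' @param tol Tolerance below one.
#' @return The qualifying scan rows.
#' @export
locate_optima <- function(scan, tol = 1e-4) {
  dplyr::filter(scan, .data$feasible, .data$optdeg >= 1 - tol)
}

#' Long (ternary-plot-ready) form of a scan
#'
#' @param scan A [scan_compositions()] result.
#' @return Tibble with `species`, `fraction` and the metric columns.
#' @export
scan_long <- function(scan) {
  sp <- attr(scan, "species")
  tidyr::pivot_longer(tibble::as_tibble(scan),
                      cols = dplyr::all_of(paste0("F_", sp)),
                      names_to = "species", names_prefix = "F_",
                      values_to = "fraction")
}

#' Write a scan grid to disk
#'
#' Tidy CSV (one row per composition/growth-rate pair, 6 significant
#' digits) or JSON.
#'
#' @param scan A [scan_compositions()] result.
#' @param path Output file; format chosen by extension (`.csv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  out <- dplyr::mutate(tibble::as_tibble(scan),
                       dplyr::across(dplyr::where(is.numeric),
                                     ~ signif(.x, 6)))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, digits = NA, na = "null")
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}
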