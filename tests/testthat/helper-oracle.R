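# Independent LP oracle: brute-force enumeration of the basic solutions of
#   optimize c'x  s.t.  A x = b, lb <= x <= ub.
# Every vertex of the polytope has n - m variables at a bound for some
# nonsingular basis; enumerate all bases and all bound assignments of the
# nonbasic variables, keep the feasible points, and take the best
# objective. Exponential, fine for n <= 8.
brute_lp <- function(obj, A_eq, b_eq, lb, ub, sense = "max", tol = 1e-7) {
  A_eq <- as.matrix(A_eq)
  n <- length(obj)
  # reduce to a maximal independent row set (consistency is checked against
  # the full system when testing feasibility of candidate points)
  A_full <- A_eq
  b_full <- b_eq
  if (nrow(A_eq) > 0L) {
    qrt <- qr(t(A_eq))
    keep <- qrt$pivot[seq_len(qrt$rank)]
    A_eq <- A_eq[keep, , drop = FALSE]
    b_eq <- b_eq[keep]
  }
  m <- nrow(A_eq)
  best <- NULL
  feasible_pt <- function(x) {
    all(x >= lb - tol) && all(x <= ub + tol) &&
      (nrow(A_full) == 0L || max(abs(A_full %*% x - b_full)) <= tol)
  }
  consider <- function(x) {
    if (!feasible_pt(x)) return()
    v <- sum(obj * x)
    if (is.null(best) ||
        (sense == "max" && v > best) || (sense == "min" && v < best)) {
      best <<- v
    }
  }
  if (m == 0L) {
    grid <- expand.grid(rep(list(c(1, 2)), n))
    for (i in seq_len(nrow(grid))) {
      x <- ifelse(grid[i, ] == 1, lb, ub)
      consider(as.numeric(x))
    }
    return(best)
  }
  bases <- utils::combn(n, min(m, n), simplify = FALSE)
  for (basis in bases) {
    B <- A_eq[, basis, drop = FALSE]
    if (nrow(B) != length(basis)) next
    if (abs(det(B)) < 1e-10) next
    nonbasic <- setdiff(seq_len(n), basis)
    k <- length(nonbasic)
    assigns <- if (k == 0L) list(integer(0)) else
      asplit(as.matrix(expand.grid(rep(list(c(1L, 2L)), k))), 1)
    for (a in assigns) {
      x <- numeric(n)
      if (k > 0L) {
        x[nonbasic] <- ifelse(a == 1L, lb[nonbasic], ub[nonbasic])
      }
      rhs <- b_eq - if (k > 0L)
        A_eq[, nonbasic, drop = FALSE] %*% x[nonbasic] else 0
      xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x[basis] <- xb
      consider(x)
    }
  }
  best
}

# Random small metabolic-network-like LP: random sparse stoichiometry over
# a few internal metabolites, nonnegative fluxes with finite caps, feasible
# by construction (x = 0 satisfies N x = 0).
random_net_lp <- function(n_rxn = 6, n_met = 3) {
  A <- matrix(stats::rbinom(n_met * n_rxn, 1, 0.6) *
                sample(c(-2, -1, 1, 2), n_met * n_rxn, TRUE),
              n_met, n_rxn)
  lb <- rep(0, n_rxn)
  ub <- stats::runif(n_rxn, 1, 10)
  obj <- stats::runif(n_rxn, -1, 1)
  list(obj = obj, A = A, b = rep(0, n_met), lb = lb, ub = ub)
}

# Random general LP with interior feasible point x0 (bounds may be
# negative), b = A x0.
random_feasible_lp <- function(n = 6, m = 3) {
  A <- matrix(stats::rnorm(m * n), m, n)
  lb <- stats::runif(n, -5, 0)
  ub <- lb + stats::runif(n, 1, 6)
  x0 <- lb + (ub - lb) * stats::runif(n)
  list(obj = stats::rnorm(n), A = A, b = as.numeric(A %*% x0),
       lb = lb, ub = ub)
}
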