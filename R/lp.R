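# Linear-programming layer used by all flux computations.
#
# Problems arrive in the constraint-based form
#   optimize  c' x
#   s.t.      A_eq x  = b_eq
#             A_leq x <= b_leq   (optional general rows)
#             lb <= x <= ub
# and are reduced to the standard form solved by simplex_core():
# variables with lb == ub are substituted out, the rest are shifted by
# their (finite) lower bound so they are nonnegative, finite upper bounds
# and general inequality rows get slack variables. All model bounds are
# finite by construction (the loaders apply the COBRA default of +-1000
# where a bound is absent), so the shift is always available.

#' Solve a bounded linear program
#'
#' Low-level solver behind [fba()], [flux_extremum()] and the fractional
#' programs in the composition scanner. Not usually called directly.
#'
#' @param obj Numeric objective coefficient vector (length `n`).
#' @param A_eq,b_eq Equality constraints `A_eq x = b_eq` (matrix may have
#'   zero rows).
#' @param lb,ub Numeric bounds, all finite, `lb <= ub`.
#' @param sense `"max"` or `"min"`.
#' @param A_leq,b_leq Optional additional inequality rows `A_leq x <= b_leq`.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`
#'   or `"unsolved"`), `x` (solution vector on the original scale, `NA`
#'   unless optimal) and `objval`.
#' @keywords internal
#' @export
solve_lp <- function(obj, A_eq, b_eq, lb, ub, sense = c("max", "min"),
                     A_leq = NULL, b_leq = NULL) {
  sense <- match.arg(sense)
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("solve_lp requires finite bounds; apply default bounds first")
  }
  fail <- function(status) {
    list(status = status, x = rep(NA_real_, n), objval = NA_real_)
  }
  if (any(lb > ub + 1e-12)) return(fail("infeasible"))
  A_eq <- as.matrix(A_eq)
  if (is.null(A_leq)) {
    A_leq <- matrix(0, 0L, n)
    b_leq <- numeric(0)
  } else {
    A_leq <- as.matrix(A_leq)
  }

  # substitute out fixed variables (lb == ub)
  fixed <- abs(ub - lb) <= 1e-12
  xfix <- numeric(n)
  xfix[fixed] <- lb[fixed]
  free <- which(!fixed)
  if (length(free) == 0L) {
    feas_eq <- nrow(A_eq) == 0L || max(abs(A_eq %*% xfix - b_eq)) <= 1e-7
    feas_le <- nrow(A_leq) == 0L || all(A_leq %*% xfix - b_leq <= 1e-7)
    if (feas_eq && feas_le) {
      return(list(status = "optimal", x = xfix, objval = sum(obj * xfix)))
    }
    return(fail("infeasible"))
  }
  b_eq <- b_eq - as.vector(A_eq %*% xfix)
  b_leq <- b_leq - as.vector(A_leq %*% xfix)
  A_eq <- A_eq[, free, drop = FALSE]
  A_leq <- A_leq[, free, drop = FALSE]

  # shift y = x - lb so y >= 0; finite spans become slack rows
  shift <- lb[free]
  b_eq <- b_eq - as.vector(A_eq %*% shift)
  b_leq <- b_leq - as.vector(A_leq %*% shift)
  span <- ub[free] - lb[free]
  nf <- length(free)
  ub_rows <- diag(nf)
  A_ineq <- rbind(A_leq, ub_rows)
  b_ineq <- c(b_leq, span)

  n_slack <- nrow(A_ineq)
  A_std <- cbind(rbind(A_eq, A_ineq),
                 rbind(matrix(0, nrow(A_eq), n_slack), diag(n_slack)))
  b_std <- c(b_eq, b_ineq)
  c_std <- c(if (sense == "max") -obj[free] else obj[free],
             numeric(n_slack))

  res <- simplex_core(c_std, A_std, b_std)
  if (res$status != "optimal") return(fail(res$status))
  x <- xfix
  x[free] <- res$x[seq_len(nf)] + shift
  list(status = "optimal", x = x, objval = sum(obj * x))
}
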