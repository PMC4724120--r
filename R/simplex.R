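# Two-phase primal simplex for the standard-form LP
#     minimize c' x   s.t.   A x = b,  x >= 0
# with Bland's anti-cycling pivot rule throughout. Dense tableau
# implementation: problem sizes in this package are small (tens of
# variables), so robustness is worth far more than sparse speed.
#
# Phase 1 minimizes the sum of artificial variables from the all-artificial
# basis; redundant equality rows are dropped when their artificial cannot be
# pivoted out. Phase 2 then minimizes c over the feasible basis. Both cost
# rows are carried in the tableau and updated together.

sx_pivot <- function(tab, prow, pcol) {
  tab[prow, ] <- tab[prow, ] / tab[prow, pcol]
  other <- setdiff(seq_len(nrow(tab)), prow)
  tab[other, ] <- tab[other, ] - outer(tab[other, pcol], tab[prow, ])
  tab
}

# Bland-rule phase loop; cost_row indexes the reduced-cost row in tab,
# allowed the columns permitted to enter, m the number of constraint rows.
sx_phase <- function(tab, basis, m, cost_row, allowed, tol, max_iter) {
  rhs_col <- ncol(tab)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      return(list(status = "iteration_limit", tab = tab, basis = basis))
    }
    red <- tab[cost_row, allowed]
    ent <- which(red < -tol)
    if (!length(ent)) return(list(status = "done", tab = tab, basis = basis))
    pcol <- allowed[ent[1L]]                     # Bland: smallest index
    col <- tab[seq_len(m), pcol]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", tab = tab, basis = basis))
    }
    ratio <- tab[pos, rhs_col] / col[pos]
    best <- pos[ratio <= min(ratio) + tol]
    prow <- best[which.min(basis[best])]         # Bland tie-break
    tab <- sx_pivot(tab, prow, pcol)
    basis[prow] <- pcol
  }
}

simplex_core <- function(cc, A, b, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  if (m == 0L) {
    if (any(cc < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = numeric(n), obj = 0))
  }
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  rhs_col <- n + m + 1L
  tab <- matrix(0, m + 2L, rhs_col)
  tab[seq_len(m), seq_len(n)] <- A
  tab[seq_len(m), n + seq_len(m)] <- diag(m)
  tab[seq_len(m), rhs_col] <- b
  tab[m + 1L, seq_len(n)] <- cc                  # phase-2 reduced costs
  tab[m + 2L, seq_len(n)] <- -colSums(A)         # phase-1 reduced costs
  tab[m + 2L, rhs_col] <- -sum(b)
  basis <- n + seq_len(m)

  ph1 <- sx_phase(tab, basis, m, m + 2L, seq_len(n + m), tol, max_iter)
  if (ph1$status != "done") return(list(status = "unsolved"))
  tab <- ph1$tab
  basis <- ph1$basis
  if (-tab[m + 2L, rhs_col] > 1e-7) return(list(status = "infeasible"))

  # drive artificials out of the basis; rows that cannot pivot are redundant
  redundant <- integer(0)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      cand <- which(abs(tab[i, seq_len(n)]) > tol)
      if (length(cand)) {
        tab <- sx_pivot(tab, i, cand[1L])
        basis[i] <- cand[1L]
      } else {
        redundant <- c(redundant, i)
      }
    }
  }
  if (length(redundant)) {
    tab <- tab[-redundant, , drop = FALSE]
    basis <- basis[-redundant]
    m <- m - length(redundant)
    if (m == 0L) {
      if (any(cc < -tol)) return(list(status = "unbounded"))
      return(list(status = "optimal", x = numeric(n), obj = 0))
    }
  }

  # phase 2: artificial columns barred from entering
  ph2 <- sx_phase(tab, basis, m, m + 1L, seq_len(n), tol, max_iter)
  if (ph2$status == "iteration_limit") return(list(status = "unsolved"))
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  tab <- ph2$tab
  basis <- ph2$basis

  x <- numeric(n)
  in_x <- basis <= n
  x[basis[in_x]] <- tab[which(in_x), ncol(tab)]
  x[x < 0 & x > -1e-9] <- 0
  list(status = "optimal", x = x, obj = sum(cc * x))
}
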