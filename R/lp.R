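# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# The flux-balance problems this package solves are small (tens of
# variables) but frequently degenerate; a deterministic, tolerance-robust
# solver matters more than speed, and no dedicated LP package is assumed.
# Standard form: min cost'x s.t. A x = b, x >= 0, b >= 0.

simplex_pivot <- function(A, b, basis, i, j) {
  pv <- A[i, j]
  A[i, ] <- A[i, ] / pv
  b[i] <- b[i] / pv
  other <- setdiff(seq_len(nrow(A)), i)
  f <- A[other, j]
  A[other, ] <- A[other, , drop = FALSE] - outer(f, A[i, ])
  b[other] <- b[other] - f * b[i]
  b[b < 0 & b > -1e-11] <- 0
  basis[i] <- j
  list(A = A, b = b, basis = basis)
}

simplex_iterate <- function(A, b, cost, basis, allowed, tol = 1e-9,
                            maxit = 10000L) {
  m <- nrow(A)
  for (it in seq_len(maxit)) {
    red <- cost - as.numeric(cost[basis] %*% A)
    red[basis] <- 0
    enter <- which(allowed & red < -tol)
    if (!length(enter))
      return(list(status = 1L, A = A, b = b, basis = basis,
                  value = sum(cost[basis] * b)))
    j <- enter[1L]                      # Bland: smallest eligible index
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = 2L))   # unbounded
    ratios <- b[pos] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol * max(1, abs(rmin))]
    i <- cand[which.min(basis[cand])]   # Bland tie-break on leaving index
    up <- simplex_pivot(A, b, basis, i, j)
    A <- up$A; b <- up$b; basis <- up$basis
  }
  list(status = 0L)                     # iteration limit
}

# min/max cost'x s.t. eq rows A x = b (any sign), x >= 0.
simplex_standard <- function(cost, A, b, maximize = FALSE, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  cost2 <- if (maximize) -cost else cost
  # phase 1: artificial basis
  Aa <- cbind(A, diag(m))
  basis <- n + seq_len(m)
  p1 <- simplex_iterate(Aa, b, c(rep(0, n), rep(1, m)), basis,
                        allowed = c(rep(TRUE, n), rep(FALSE, m)), tol = tol)
  if (p1$status != 1L || p1$value > 1e-7) return(list(status = -1L))
  Aa <- p1$A; b <- p1$b; basis <- p1$basis
  # drive residual artificials out of the basis (or drop redundant rows)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] <= n) next
    j <- which(abs(Aa[i, seq_len(n)]) > tol)
    j <- setdiff(j, basis)
    if (length(j)) {
      up <- simplex_pivot(Aa, b, basis, i, j[1L])
      Aa <- up$A; b <- up$b; basis <- up$basis
    } else keep[i] <- FALSE             # redundant constraint row
  }
  if (!all(keep)) {
    Aa <- Aa[keep, , drop = FALSE]; b <- b[keep]; basis <- basis[keep]
  }
  p2 <- simplex_iterate(Aa, b, c(cost2, rep(0, m)), basis,
                        allowed = c(rep(TRUE, n), rep(FALSE, m)), tol = tol)
  if (p2$status != 1L) return(list(status = -abs(p2$status)))
  x <- numeric(n)
  inb <- p2$basis <= n
  x[p2$basis[inb]] <- p2$b[inb]
  list(status = 1L, x = x, value = sum(cost * x))
}

# Bounded-variable LP: max/min obj'v subject to Aeq v = beq,
# ineq_A v <= ineq_b and lb <= v <= ub. Shifts to y = v - lb >= 0, adds
# slack variables for the upper bounds and inequality rows, and solves in
# standard form.
lp_bounded <- function(obj, Aeq, beq, lb, ub,
                       ineq_A = NULL, ineq_b = NULL,
                       maximize = TRUE, big = 1e4, eps = 1e-9) {
  n <- length(obj)
  lb <- pmax(lb, -big)
  ub <- pmin(ub, big)
  if (any(lb > ub + 1e-12)) return(list(status = -1L, x = NULL, value = NA_real_))
  # variables pinned by equal bounds are substituted out
  fixed <- (ub - lb) < 1e-12
  if (all(fixed)) {
    x <- lb
    ok <- max(abs(Aeq %*% x - beq)) < 1e-8 &&
      (is.null(ineq_A) || all(ineq_A %*% x <= ineq_b + 1e-8))
    return(if (ok) list(status = 1L, x = x, value = sum(obj * x))
           else list(status = -1L, x = NULL, value = NA_real_))
  }
  if (any(fixed)) {
    xf <- lb[fixed]
    beq2 <- as.numeric(beq - Aeq[, fixed, drop = FALSE] %*% xf)
    ineq_b2 <- if (!is.null(ineq_A))
      as.numeric(ineq_b - ineq_A[, fixed, drop = FALSE] %*% xf)
    sub <- lp_bounded(obj[!fixed], Aeq[, !fixed, drop = FALSE], beq2,
                      lb[!fixed], ub[!fixed],
                      ineq_A = if (!is.null(ineq_A)) ineq_A[, !fixed, drop = FALSE],
                      ineq_b = ineq_b2, maximize = maximize, big = big, eps = eps)
    if (sub$status != 1L) return(sub)
    x <- numeric(n)
    x[fixed] <- xf
    x[!fixed] <- sub$x
    return(list(status = 1L, x = x, value = sum(obj * x)))
  }
  span <- ub - lb
  nineq <- if (is.null(ineq_A)) 0L else nrow(ineq_A)
  # columns: y (n), slack_ub (n), slack_ineq (nineq)
  ncol_tot <- 2L * n + nineq
  rows_ub <- cbind(diag(n), diag(n),
                   matrix(0, n, nineq))
  rows_eq <- cbind(Aeq, matrix(0, nrow(Aeq), n + nineq))
  A <- rbind(rows_ub, rows_eq)
  b <- c(span, as.numeric(beq - Aeq %*% lb))
  if (nineq) {
    rows_in <- cbind(ineq_A, matrix(0, nineq, n), diag(nineq))
    A <- rbind(A, rows_in)
    b <- c(b, as.numeric(ineq_b - ineq_A %*% lb))
  }
  cost <- c(obj, rep(0, n + nineq))
  res <- simplex_standard(cost, A, b, maximize = maximize, tol = eps)
  if (res$status != 1L)
    return(list(status = as.integer(res$status), x = NULL, value = NA_real_))
  x <- lb + res$x[seq_len(n)]
  list(status = 1L, x = x, value = sum(obj * x))
}
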