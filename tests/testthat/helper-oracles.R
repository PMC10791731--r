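# Independent oracles used across the suite. Both are deliberately written
# against different formulations than the package code paths they check.

# Brute-force LP oracle: enumerate basic feasible solutions of
#   max c'x  s.t.  A x = b, l <= x <= u
# by fixing every (n - m)-subset of variables at a bound and solving the
# square system for the rest. Only usable for tiny problems.
lp_enumerate <- function(cc, A, b, l, u) {
  n <- length(cc); m <- nrow(A)
  best <- -Inf; bestx <- NULL
  basis_sets <- utils::combn(n, min(m, n))
  for (k in seq_len(ncol(basis_sets))) {
    Bi <- basis_sets[, k]
    Ni <- setdiff(seq_len(n), Bi)
    grid <- if (length(Ni))
      expand.grid(rep(list(c(1L, 2L)), length(Ni)))
    else data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      xN <- if (length(Ni)) ifelse(unlist(grid[g, ]) == 1L, l[Ni], u[Ni])
            else numeric(0)
      if (any(!is.finite(xN))) next
      rhs <- b - if (length(Ni)) A[, Ni, drop = FALSE] %*% xN else 0
      xB <- tryCatch(solve(A[, Bi, drop = FALSE], rhs),
                     error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n); x[Ni] <- xN; x[Bi] <- xB
      if (all(x >= l - 1e-9) && all(x <= u + 1e-9)) {
        v <- sum(cc * x)
        if (v > best) { best <- v; bestx <- x }
      }
    }
  }
  list(value = best, x = bestx)
}

# SIMPLS oracle for single-response PLS (de Jong 1993): computes the
# regression coefficients of autoscaled PLS1 by a projection recursion that
# shares no code with the NIPALS implementation.
simpls1_coef <- function(X, y, ncomp) {
  Xs <- scale(X); ys <- as.numeric(scale(y))
  s <- as.numeric(crossprod(Xs, ys))
  p_basis <- NULL
  R <- matrix(0, ncol(Xs), ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    r <- s
    t_ <- as.numeric(Xs %*% r)
    tn <- sqrt(sum(t_^2))
    t_ <- t_ / tn; r <- r / tn
    p <- as.numeric(crossprod(Xs, t_))
    q[a] <- sum(ys * t_)
    v <- p
    if (!is.null(p_basis)) v <- v - p_basis %*% crossprod(p_basis, p)
    v <- v / sqrt(sum(v^2))
    p_basis <- cbind(p_basis, v)
    s <- s - as.numeric(v) * sum(as.numeric(v) * s)
    R[, a] <- r
  }
  b <- as.numeric(R %*% q)
  names(b) <- colnames(X)
  b
}

# small helper: a tiny branched metabolic model for exact LP checks
#   A -> B (v2), B -> C (v3), B -> D (v4), with exchanges for A, C, D
tiny_branch_model <- function(ub_in = 10, ub_c = 4, ub_d = 3) {
  mets <- data.frame(id = c("A[c]", "B[c]", "C[c]", "D[c]"),
                     name = c("A", "B", "C", "D"), compartment = "c")
  rxns <- list(
    reaction("EX_A", c("A[c]" = -1), lb = -ub_in, ub = 0),
    reaction("AB", c("A[c]" = -1, "B[c]" = 1)),
    reaction("BC", c("B[c]" = -1, "C[c]" = 1), ub = ub_c),
    reaction("BD", c("B[c]" = -1, "D[c]" = 1), ub = ub_d),
    reaction("EX_C", c("C[c]" = -1)),
    reaction("EX_D", c("D[c]" = -1)))
  metabolic_model(mets, rxns, objective = "EX_C", id = "tiny")
}
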