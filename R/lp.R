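## Linear programming --------------------------------------------------------
##
## Bounded-variable two-phase revised simplex with Bland's anti-cycling rule.
## Flux-balance problems are small but heavily degenerate (every equality
## right-hand side is zero), so the implementation favours determinism and
## robustness over speed: Bland's pivoting rule guarantees termination, and
## basic solutions are recomputed from a fresh factorisation every iteration.

#' Solve a bounded linear program with equality constraints
#'
#' Solves `max/min c'x` subject to `A_eq x = b_eq`, optional `A_le x <= b_le`
#' (handled via slack variables) and finite lower bounds `lb <= x <= ub`
#' (`ub` may be infinite). Deterministic: identical inputs give identical
#' solutions.
#'
#' @param objective numeric objective coefficients (length n).
#' @param A_eq,b_eq equality constraint matrix (m x n) and right-hand side.
#' @param lb,ub variable bounds; `lb` finite.
#' @param A_le,b_le optional inequality block `A_le x <= b_le`.
#' @param maximize maximize (`TRUE`) or minimize the objective.
#' @param max_iter simplex iteration cap per phase.
#' @param tol feasibility/optimality tolerance.
#' @return list with `status` ("optimal", "infeasible", "unbounded" or
#'   "not_converged"), `objective_value`, and the solution vector `x`.
#' @keywords internal
solve_lp <- function(objective, A_eq, b_eq, lb, ub, A_le = NULL, b_le = NULL,
                     maximize = TRUE, max_iter = 20000L, tol = 1e-9) {
  n <- length(objective)
  stopifnot(ncol(A_eq) == n, length(lb) == n, length(ub) == n,
            nrow(A_eq) == length(b_eq))
  if (any(!is.finite(lb))) stop("solve_lp() requires finite lower bounds")
  if (any(lb > ub + 1e-12)) stop("inconsistent bounds: lb > ub")

  A <- A_eq; b <- b_eq; cc <- objective; l <- lb; u <- ub
  if (!is.null(A_le)) {
    stopifnot(ncol(A_le) == n, nrow(A_le) == length(b_le))
    k <- nrow(A_le)
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(A_le, diag(k)))
    b <- c(b, b_le)
    cc <- c(cc, rep(0, k))
    l <- c(l, rep(0, k)); u <- c(u, rep(Inf, k))
  }
  res <- bounded_simplex(if (maximize) cc else -cc, A, b, l, u,
                         max_iter = max_iter, tol = tol)
  x <- res$x[seq_len(n)]
  names(x) <- colnames(A_eq)
  obj <- if (res$status == "optimal") sum(objective * x) else NA_real_
  list(status = res$status, objective_value = obj, x = x)
}

## maximize c'x s.t. A x = b, l <= x <= u  (l finite; u may be Inf)
bounded_simplex <- function(cc, A, b, l, u, max_iter = 20000L, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)

  ## phase 1: artificials close the residual of the all-at-lower-bound point
  x <- l
  r <- as.numeric(b - A %*% x)
  asign <- ifelse(r >= 0, 1, -1)
  Af <- cbind(A, diag(asign, m))
  lf <- c(l, rep(0, m))
  uf <- c(u, rep(Inf, m))
  xf <- c(x, abs(r))
  basis <- n + seq_len(m)
  stat <- c(rep(1L, n), rep(0L, m))   # 0 basic, 1 at lower, 2 at upper
  c1 <- c(rep(0, n), rep(-1, m))      # maximize -(sum of artificials)

  p1 <- simplex_core(c1, Af, b, lf, uf, xf, basis, stat, max_iter, tol)
  if (p1$status == "not_converged") return(list(status = "not_converged", x = x))
  if (sum(p1$x[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", x = p1$x[seq_len(n)]))

  ## phase 2: freeze artificials at zero and optimize the real objective
  uf2 <- uf; uf2[n + seq_len(m)] <- 0
  xf2 <- p1$x; xf2[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  p2 <- simplex_core(c2, Af, b, lf, uf2, xf2, p1$basis, p1$stat, max_iter, tol)
  list(status = p2$status, x = p2$x[seq_len(n)])
}

simplex_core <- function(cc, A, b, l, u, x, basis, stat, max_iter, tol) {
  m <- nrow(A)
  for (it in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    nb <- which(stat != 0L)
    ## refresh basic values from the nonbasic point (numerical hygiene)
    rhs <- b - A[, nb, drop = FALSE] %*% x[nb]
    xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(xB)) return(list(status = "not_converged", x = x,
                                 basis = basis, stat = stat))
    x[basis] <- as.numeric(xB)

    y <- as.numeric(solve(t(B), cc[basis]))
    d <- cc[nb] - as.numeric(crossprod(A[, nb, drop = FALSE], y))
    improving <- (stat[nb] == 1L & d > tol) | (stat[nb] == 2L & d < -tol)
    if (!any(improving)) {
      return(list(status = "optimal", x = x, basis = basis, stat = stat))
    }
    e <- nb[improving][which.min(nb[improving])]     # Bland: smallest index
    de <- if (stat[e] == 1L) 1 else -1               # direction of x_e
    w <- as.numeric(solve(B, A[, e])) * de           # x_B changes by -w * t

    ## ratio test: keep basic variables inside their bounds
    tmax_basic <- Inf; leave <- NA_integer_
    for (i in seq_len(m)) {
      wi <- w[i]
      if (wi > tol) ti <- (x[basis[i]] - l[basis[i]]) / wi
      else if (wi < -tol) ti <- (u[basis[i]] - x[basis[i]]) / (-wi)
      else next
      if (ti < tmax_basic - 1e-12 ||
          (ti < tmax_basic + 1e-12 && (is.na(leave) || basis[i] < basis[leave]))) {
        tmax_basic <- ti; leave <- i
      }
    }
    tflip <- u[e] - l[e]
    t_step <- min(tmax_basic, tflip)
    if (!is.finite(t_step)) return(list(status = "unbounded", x = x,
                                        basis = basis, stat = stat))
    t_step <- max(t_step, 0)
    x[e] <- x[e] + de * t_step
    x[basis] <- x[basis] - w * t_step
    if (tflip <= tmax_basic + 1e-12 && is.finite(tflip) &&
        (is.na(leave) || tflip < tmax_basic + 1e-12)) {
      if (tflip <= tmax_basic) {
        stat[e] <- if (stat[e] == 1L) 2L else 1L     # bound flip, basis fixed
        next
      }
    }
    ## pivot: e enters, basis[leave] goes to the bound it hit
    lv <- basis[leave]
    hit_lower <- w[leave] > 0
    x[lv] <- if (hit_lower) l[lv] else u[lv]
    stat[lv] <- if (hit_lower) 1L else 2L
    basis[leave] <- e
    stat[e] <- 0L
  }
  list(status = "not_converged", x = x, basis = basis, stat = stat)
}
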