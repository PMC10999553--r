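# LP/QP back-ends.
#
# LP: a dense bounded-variable primal simplex (two phases, Bland's rule
# for anti-cycling), written for the small, often degenerate problems
# constraint-based analysis produces. Problems are solved in the natural
# form  max c'v  s.t.  A v = b, lb <= v <= ub;  inequality side
# constraints (the FVA objective cut) enter through slack variables.
# Redundant steady-state rows are tolerated: their artificials simply
# stay basic at zero after phase 1.
#
# QP: quadprog::solve.QP (Goldfarb-Idnani dual method). The steady-state
# rows are reduced to full row rank first (solve.QP rejects dependent
# equality constraints) and variables with lb == ub are pinned by
# equality rows instead of a degenerate bound pair.

BIG_BOUND <- 1000

# Bounded-variable simplex. Returns list(status, x, objective).
simplex_bv <- function(obj, A, b, lb, ub, maximize = TRUE,
                       tol = 1e-9, max_iter = 10000L) {
  n <- length(obj)
  m <- nrow(A)
  if (!maximize) obj <- -obj
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible"))

  # augment with artificials for phase 1; nonbasic variables must start ON
  # a bound (the finite one nearest zero), matching the at_upper flags the
  # iterations reconstruct the point from
  start_upper <- is.finite(ub) & (!is.finite(lb) | abs(ub) < abs(lb))
  x <- ifelse(start_upper, ub, lb)
  r <- b - as.vector(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(sgn, m))
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(Inf, m))
  ntot <- n + m

  basis <- n + seq_len(m)
  at_upper <- c(start_upper, rep(FALSE, m))   # nonbasic side flags
  xval <- c(x, abs(r))

  run_phase <- function(cost, basis, at_upper, xval, lball, uball) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit"))
      Bmat <- Aall[, basis, drop = FALSE]
      qB <- qr(Bmat)
      if (qB$rank < m) return(list(status = "singular_basis"))
      # current basic values from nonbasic pattern
      nb <- setdiff(seq_len(ntot), basis)
      xN <- ifelse(at_upper[nb], uball[nb], lball[nb])
      xN[!is.finite(xN)] <- 0
      rhs <- b - as.vector(Aall[, nb, drop = FALSE] %*% xN)
      xB <- qr.coef(qB, rhs)
      y <- qr.coef(qr(t(Bmat)), cost[basis])
      d <- cost[nb] - as.vector(t(Aall[, nb, drop = FALSE]) %*% y)

      movable <- (uball[nb] - lball[nb]) > tol    # fixed variables cannot enter
      enter_ok <- movable &
        ((!at_upper[nb] & d > tol) | (at_upper[nb] & d < -tol))
      if (!any(enter_ok)) {
        xfull <- numeric(ntot)
        xfull[nb] <- xN
        xfull[basis] <- xB
        return(list(status = "optimal", basis = basis, at_upper = at_upper,
                    x = xfull, objective = sum(cost * xfull)))
      }
      e_rel <- which(enter_ok)[which.min(nb[enter_ok])]   # Bland: smallest index
      e <- nb[e_rel]
      dirn <- if (at_upper[e]) -1 else 1                 # movement of x_e
      w <- qr.coef(qB, Aall[, e])                        # xB changes by -w * dirn * step

      step <- uball[e] - lball[e]                        # bound-flip limit
      leave <- 0L                                        # 0 = bound flip
      for (k in seq_len(m)) {
        delta <- -w[k] * dirn
        if (delta < -tol) {                              # basic k decreasing
          lim <- (xB[k] - lball[basis[k]]) / (-delta)
        } else if (delta > tol) {                        # basic k increasing
          lim <- (uball[basis[k]] - xB[k]) / delta
        } else next
        if (!is.finite(lim)) next
        if (lim < step - tol || (lim < step + tol && leave != 0L &&
                                 basis[k] < basis[leave])) {
          step <- lim
          leave <- k
        }
      }
      if (!is.finite(step)) return(list(status = "unbounded"))
      step <- max(step, 0)

      if (leave == 0L) {                                 # flip e to other bound
        at_upper[e] <- !at_upper[e]
      } else {
        lv <- basis[leave]
        delta <- -w[leave] * dirn
        at_upper[lv] <- delta > 0                        # side it hit
        basis[leave] <- e
        at_upper[e] <- FALSE                             # now basic; flag unused
      }
    }
  }

  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(cost1, basis, at_upper, xval, lball, uball)
  if (p1$status != "optimal") return(list(status = "infeasible"))
  if (sum(p1$x[n + seq_len(m)]) > 1e-7) return(list(status = "infeasible"))

  # phase 2: pin artificials at zero, optimise the real objective
  uball[n + seq_len(m)] <- 0
  cost2 <- c(obj, rep(0, m))
  p2 <- run_phase(cost2, p1$basis, p1$at_upper, p1$x, lball, uball)
  if (p2$status == "unbounded") return(list(status = "unbounded"))
  if (p2$status != "optimal") return(list(status = "infeasible"))
  v <- p2$x[seq_len(n)]
  v <- pmin(pmax(v, lb), ub)
  list(status = "optimal", x = v,
       objective = if (maximize) sum(obj * v) else -sum(obj * v))
}

# FBA-shaped interface: max/min obj'v s.t. S v = 0, bounds, optional
# extra inequality rows  ineq_A v <= ineq_b  (added through slacks).
solve_lp <- function(obj, S, lb, ub, maximize = TRUE,
                     ineq_A = NULL, ineq_b = NULL, tol = 1e-9) {
  n <- length(obj)
  lb <- pmax(lb, -BIG_BOUND * 1e3)
  ub <- pmin(ub, BIG_BOUND * 1e3)
  A <- S
  b <- rep(0, nrow(S))
  if (!is.null(ineq_A)) {
    ineq_A <- matrix(ineq_A, ncol = n)
    k <- nrow(ineq_A)
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(ineq_A, diag(1, k)))
    b <- c(b, ineq_b)
    lb <- c(lb, rep(0, k))
    ub <- c(ub, rep(Inf, k))
    obj <- c(obj, rep(0, k))
  }
  res <- simplex_bv(obj, A, b, lb, ub, maximize = maximize, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, x = NULL))
  }
  list(status = "optimal",
       objective = sum(obj[seq_len(n)] * res$x[seq_len(n)]),
       x = res$x[seq_len(n)])
}

solve_qp_bounded <- function(ref, S, lb, ub) {
  n <- length(ref)
  lb <- pmax(lb, -BIG_BOUND * 1e3)
  ub <- pmin(ub, BIG_BOUND * 1e3)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", x = NULL))

  fixed <- which(ub - lb < 1e-10)
  free <- setdiff(seq_len(n), fixed)

  Eq <- S
  beq <- rep(0, nrow(S))
  if (length(fixed)) {
    P <- matrix(0, length(fixed), n)
    P[cbind(seq_along(fixed), fixed)] <- 1
    Eq <- rbind(Eq, P)
    beq <- c(beq, (lb[fixed] + ub[fixed]) / 2)
  }
  qrE <- qr(t(Eq))
  indep <- qrE$pivot[seq_len(qrE$rank)]
  # consistency of dropped dependent rows is checked by the residual below
  Eq_r <- Eq[indep, , drop = FALSE]
  beq_r <- beq[indep]

  Ineq <- rbind(diag(n)[free, , drop = FALSE], -diag(n)[free, , drop = FALSE])
  bineq <- c(lb[free], -ub[free])

  Amat <- t(rbind(Eq_r, Ineq))
  bvec <- c(beq_r, bineq)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = ref, Amat = Amat, bvec = bvec,
                       meq = nrow(Eq_r)),
    error = function(e) NULL
  )
  if (is.null(sol)) return(list(status = "infeasible", x = NULL))
  if (max(abs(Eq %*% sol$solution - beq)) > 1e-6) {
    return(list(status = "infeasible", x = NULL))
  }
  list(status = "optimal", x = sol$solution)
}
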