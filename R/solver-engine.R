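# Thin port to the quadratic-programming engine (quadprog::solve.QP,
# Goldfarb-Idnani dual active set). All flux-level routines (FBA, FVA,
# GIMME, MoMA, leak and task checks) go through .lp() and .qpMoma().
#
# Linear programs are solved by bisection on the objective level: each
# probe "is there a feasible point with c'v >= t?" is a strictly convex
# minimum-norm QP, which the dual active-set method solves exactly and
# detects infeasibility reliably. The returned flux vector is the
# minimum-norm point of the final near-optimal slice, so degenerate
# optimal faces yield a deterministic, reproducible representative
# rather than an arbitrary vertex.

.BIGCAP <- 1e4

# Build the constraint system shared by the solvers: equality rows
# (Aeq v = beq, plus variables pinned by lb == ub) are rank-reduced so
# quadprog never sees linearly dependent equalities (mass-conserving
# networks always carry dependent rows of S); inequalities are bounds on
# the free variables plus optional Ale v <= ble rows.
.lpSystem <- function(Aeq, beq, lb, ub, Ale = NULL, ble = NULL) {
  n <- length(lb)
  Aeq <- as.matrix(Aeq)
  fixed <- which((ub - lb) < 1e-12)
  if (length(fixed)) {
    E <- matrix(0, length(fixed), n)
    E[cbind(seq_along(fixed), fixed)] <- 1
    Aeq <- rbind(Aeq, E)
    beq <- c(beq, lb[fixed])
  }
  # consistency of the full equality system before dropping rows
  xp <- qr.coef(qr(Aeq), beq)
  xp[is.na(xp)] <- 0
  if (max(abs(Aeq %*% xp - beq)) > 1e-7 * max(1, max(abs(beq)))) {
    return(NULL)
  }
  qa <- qr(t(Aeq))
  keep <- sort(qa$pivot[seq_len(qa$rank)])
  Aeq <- Aeq[keep, , drop = FALSE]
  beq <- beq[keep]
  free <- setdiff(seq_len(n), fixed)
  Ain <- rbind(
    diag(n)[free, , drop = FALSE],
    -diag(n)[free, , drop = FALSE],
    if (!is.null(Ale) && nrow(Ale)) -as.matrix(Ale))
  bin <- c(lb[free], -ub[free], if (!is.null(Ale) && nrow(Ale)) -ble)
  list(Aeq = Aeq, beq = beq, Ain = Ain, bin = bin, meq = nrow(Aeq), n = n)
}

# One strictly convex QP: minimize 1/2 x'Dx - d'x over the system.
.qpCall <- function(D, d, sys) {
  A <- t(rbind(sys$Aeq, sys$Ain))
  b <- c(sys$beq, sys$bin)
  tryCatch(
    list(ok = TRUE,
         x = quadprog::solve.QP(D, d, A, b, meq = sys$meq)$solution),
    error = function(e) list(ok = FALSE, message = conditionMessage(e)))
}

# Minimum-norm feasible point of the system, optionally with the extra
# half-space c0'x >= level.
.lpFeasiblePoint <- function(sys, c0 = NULL, level = NULL) {
  if (!is.null(c0)) {
    sys$Ain <- rbind(sys$Ain, c0)
    sys$bin <- c(sys$bin, level)
  }
  .qpCall(diag(1, sys$n), numeric(sys$n), sys)
}

# Linear program:
#   optimize  obj' v   s.t.  Aeq v = beq, Ale v <= ble, lb <= v <= ub
.lp <- function(obj, Aeq, beq, lb, ub, Ale = NULL, ble = NULL,
                maximize = FALSE) {
  n <- length(obj)
  lb <- pmax(lb, -.BIGCAP)
  ub <- pmin(ub, .BIGCAP)
  bad <- list(status = "infeasible", value = NA_real_, x = rep(NA_real_, n))
  if (any(lb > ub + 1e-12)) return(bad)
  sys <- .lpSystem(Aeq, beq, lb, ub, Ale, ble)
  if (is.null(sys)) return(bad)
  sgn <- if (maximize) 1 else -1
  c0 <- sgn * obj
  base <- .lpFeasiblePoint(sys)
  if (!base$ok) return(bad)
  lo <- sum(c0 * base$x)
  hi <- sum(pmax(c0 * ub, c0 * lb)) + 1
  best <- base$x
  tol <- 1e-9
  for (i in seq_len(100L)) {
    if (hi - lo <= tol * max(1, abs(lo))) break
    mid <- (lo + hi) / 2
    r <- .lpFeasiblePoint(sys, c0, mid)
    if (r$ok) {
      best <- r$x
      lo <- max(mid, sum(c0 * r$x))
    } else {
      hi <- mid
    }
  }
  list(status = "optimal", value = sum(obj * best), x = best)
}

# Fast feasibility probe: can the system carry c0'v >= level?
.lpCanReach <- function(sys, c0, level) {
  .lpFeasiblePoint(sys, c0, level)$ok
}

# Quadratic program for MoMA:
#   minimize ||v - w||^2   s.t.  S v = 0, lb <= v <= ub
# Variables pinned by lb == ub (knocked-out reactions) are substituted
# out and the steady-state equalities eliminated through an orthonormal
# null-space basis, leaving a small, well-conditioned inequality-only QP
# in the degrees of freedom of the flux cone.
.qpMoma <- function(S, w, lb, ub) {
  S <- as.matrix(S)
  n <- length(w)
  lb <- pmax(lb, -.BIGCAP)
  ub <- pmin(ub, .BIGCAP)
  bad <- function(status) list(status = status, v = rep(NA_real_, n))
  if (any(lb > ub + 1e-12)) return(bad("infeasible"))
  fixed <- which((ub - lb) < 1e-12)
  free <- setdiff(seq_len(n), fixed)
  rhs <- if (length(fixed)) as.vector(-S[, fixed, drop = FALSE] %*% lb[fixed])
         else numeric(nrow(S))
  if (!length(free)) {
    v <- lb
    if (max(abs(S %*% v)) > 1e-7) return(bad("infeasible"))
    return(list(status = "optimal", v = v))
  }
  Sf <- S[, free, drop = FALSE]
  v0 <- qr.coef(qr(Sf), rhs)
  v0[is.na(v0)] <- 0
  if (max(abs(Sf %*% v0 - rhs)) > 1e-7 * max(1, max(abs(rhs)))) {
    return(bad("infeasible"))
  }
  qrT <- qr(t(Sf))
  rk <- qrT$rank
  k <- ncol(Sf) - rk
  wf <- w[free]; lf <- lb[free]; uf <- ub[free]
  if (k == 0L) {
    vf <- as.vector(v0)
    if (any(vf < lf - 1e-7) || any(vf > uf + 1e-7)) return(bad("infeasible"))
    vf <- pmin(pmax(vf, lf), uf)
  } else {
    N <- qr.Q(qrT, complete = TRUE)[, (rk + 1):ncol(Sf), drop = FALSE]
    D <- 2 * crossprod(N)
    d <- as.vector(2 * t(N) %*% (wf - v0))
    A <- rbind(N, -N)
    b <- c(lf - v0, v0 - uf)
    solveOnce <- function(Dm, dv, bv)
      tryCatch(quadprog::solve.QP(Dm, dv, t(A), bv),
               error = function(e) conditionMessage(e))
    # degenerate active sets can make the dual active-set method fail or
    # report a spurious inconsistency; a deterministic hair's-breadth
    # relaxation of the inequality levels breaks the degeneracy without
    # affecting the solution at the tolerances used downstream
    jit <- abs(sin(seq_along(b))) + 0.5
    r <- solveOnce(D, d, b)
    if (is.character(r)) r <- solveOnce(D + diag(1e-10, k), d, b - 1e-9 * jit)
    if (is.character(r)) r <- solveOnce(D + diag(1e-8, k), d, b - 1e-8 * jit)
    if (is.character(r)) {
      # cross-check against an independent feasibility probe before
      # declaring the knockout infeasible
      sys <- .lpSystem(S, numeric(nrow(S)), lb, ub)
      feas <- !is.null(sys) && .lpFeasiblePoint(sys)$ok
      if (!feas) return(bad("infeasible"))
      return(bad(paste("solver error:", r)))
    }
    vf <- as.vector(v0) + as.vector(N %*% r$solution)
    vf <- pmin(pmax(vf, lf), uf)
  }
  v <- numeric(n)
  v[fixed] <- lb[fixed]
  v[free] <- vf
  list(status = "optimal", v = v)
}
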