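# Linear and quadratic programming layer.
#
# Both pFBA stages are solved with the dual active-set method of
# quadprog::solve.QP. Stage 2 (minimize the squared flux norm at fixed
# substrate optimum) is a strictly convex QP solved directly. Stage 1
# (minimize substrate uptake, a pure LP) is solved by exact Tikhonov
# regularization: for a linear program, minimizing c'v + (eps/2)||v||^2
# returns, for all eps below a finite problem-dependent threshold, exactly
# the least-norm optimizer of the LP (Mangasarian & Meyer 1979). An
# eps-continuation with an agreement check detects when the threshold has
# been passed, so the reported stage-1 objective carries no regularization
# bias.

solver_defaults <- function() {
  list(feasibility_tol = 1e-9,
       optimality_tol = 1e-9,
       stage1_fix_tol = 1e-9,   # uptake fixed to optimum * (1 + tol) in stage 2
       eps_sequence = c(1e-2, 1e-4, 1e-6),
       eps_agree_tol = 1e-9,
       inf_bound = 1e30)
}

# Solve: min 0.5 v' D v + lin' v  s.t.  S v = beq, lb <= v <= ub,
# optional extra inequalities ineq_A v >= ineq_b.
# D is diagonal (given as scalar or vector). Fixed variables (lb == ub)
# become equality rows; linearly dependent equality rows are dropped by QR
# after a consistency check.
qp_core <- function(S, beq, lb, ub, quad_diag, lin,
                    ineq_A = NULL, ineq_b = NULL,
                    inf_bound = 1e30) {
  n <- length(lb)
  if (length(quad_diag) == 1) quad_diag <- rep(quad_diag, n)
  S <- as.matrix(S)
  fixed <- which(ub - lb < 1e-12)
  if (length(fixed) > 0) {
    E <- matrix(0, length(fixed), n)
    E[cbind(seq_along(fixed), fixed)] <- 1
    S <- rbind(S, E)
    beq <- c(beq, lb[fixed])
  }
  # drop dependent equality rows (consistency is verified on the solution)
  if (nrow(S) > 0) {
    qr_ <- qr(t(S))
    keep <- qr_$pivot[seq_len(qr_$rank)]
    S <- S[keep, , drop = FALSE]
    beq <- beq[keep]
  }
  free <- setdiff(seq_len(n), fixed)
  Arows <- list(); brows <- numeric(0)
  lo <- free[lb[free] > -inf_bound]
  if (length(lo) > 0) {
    M <- matrix(0, length(lo), n); M[cbind(seq_along(lo), lo)] <- 1
    Arows <- c(Arows, list(M)); brows <- c(brows, lb[lo])
  }
  hi <- free[ub[free] < inf_bound]
  if (length(hi) > 0) {
    M <- matrix(0, length(hi), n); M[cbind(seq_along(hi), hi)] <- -1
    Arows <- c(Arows, list(M)); brows <- c(brows, -ub[hi])
  }
  if (!is.null(ineq_A)) {
    Arows <- c(Arows, list(as.matrix(ineq_A))); brows <- c(brows, ineq_b)
  }
  A <- do.call(rbind, c(list(S), Arows))
  bvec <- c(beq, brows)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(quad_diag, n), dvec = -lin,
                       Amat = t(A), bvec = bvec, meq = nrow(S)),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("inconsistent|no solution", msg)) {
        stop("infeasible: constraint system has no solution (", msg, ")",
             call. = FALSE)
      }
      stop("solver failure: ", msg, call. = FALSE)
    })
  v <- sol$solution
  # verify the dropped equality rows and fixed variables were consistent
  if (length(beq) > 0) {
    resid <- max(abs(S %*% v - beq))
    if (resid > 1e-6 * max(1, max(abs(v)))) {
      stop("solver failure: equality residual ", format(resid), call. = FALSE)
    }
  }
  v
}

# Stage-1 LP: min lin'v subject to the same constraint system, via
# regularization continuation. Returns list(v, objective, eps_used).
lp_via_regularization <- function(S, beq, lb, ub, lin, settings = solver_defaults()) {
  prev <- NULL
  for (eps in settings$eps_sequence) {
    # min lin'v + (eps/2)||v||^2  ==  min (1/2)||v||^2 + (lin/eps)'v, rescaled
    v <- qp_core(S, beq, lb, ub, quad_diag = 1, lin = lin / eps,
                 inf_bound = settings$inf_bound)
    obj <- sum(lin * v)
    if (!is.null(prev)) {
      scale <- max(1, abs(prev$obj))
      if (abs(obj - prev$obj) <= settings$eps_agree_tol * scale &&
          max(abs(v - prev$v)) <= 1e-7 * max(1, max(abs(v)))) {
        return(list(v = v, objective = obj, eps_used = eps))
      }
    }
    prev <- list(v = v, obj = obj)
  }
  warning("stage-1 regularization continuation did not stabilize; ",
          "using smallest eps = ", utils::tail(settings$eps_sequence, 1))
  list(v = prev$v, objective = prev$obj, eps_used = utils::tail(settings$eps_sequence, 1))
}
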