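# Dense bounded-variable primal simplex.
#
# Solves   maximize  c'x   subject to  A x = b,  lb <= x <= ub
# with all bounds finite.  Written for the small, highly degenerate linear
# programs that arise in flux balance analysis (tens of reactions, equality
# rows that are mostly zero).  Two phases: artificial variables give the
# starting basis; after feasibility they are clamped to [0, 0] and the true
# objective is optimized.  Dantzig pricing with an automatic switch to
# Bland's rule after a run of degenerate pivots guarantees termination.
# The basic solution is recomputed from a fresh factorization at every
# iteration, so rounding error does not accumulate across pivots.

#' Solve a bounded-variable linear program
#'
#' Maximizes \code{c'x} subject to \code{A x = b} and \code{lb <= x <= ub}.
#' All bounds must be finite; callers with conceptually unbounded fluxes
#' should use a large finite cap (the packaged models use +/-1000).
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds (length n, finite).
#' @param maximize logical; if \code{FALSE} minimizes.
#' @param tol feasibility/optimality tolerance.
#' @param max_iter pivot limit per phase.
#' @return list with \code{status} ("optimal", "infeasible" or "maxit"),
#'   \code{x} (primal solution) and \code{objective}.
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  ## start every structural variable at the bound nearer zero
  at_lb <- abs(lb) <= abs(ub)
  x_nb <- ifelse(at_lb, lb, ub)
  r <- b - as.vector(A %*% x_nb)

  ## artificial block: column sign(r_i) e_i so the artificial value is |r_i|
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, nrow = m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  ntot <- n + m

  basis <- (n + 1L):ntot
  ## status of nonbasic variables: TRUE = at lower bound
  nb_at_lb <- c(at_lb, rep(TRUE, m))

  run_phase <- function(cost, basis, nb_at_lb, lbe, ube) {
    degen_run <- 0L
    bland <- FALSE
    for (it in seq_len(max_iter)) {
      Bmat <- Aext[, basis, drop = FALSE]
      is_basic <- logical(ntot)
      is_basic[basis] <- TRUE
      nonbasic <- which(!is_basic)
      xval <- numeric(ntot)
      xval[nonbasic] <- ifelse(nb_at_lb[nonbasic], lbe[nonbasic], ube[nonbasic])
      rhs <- b - as.vector(Aext[, nonbasic, drop = FALSE] %*% xval[nonbasic])
      xB <- tryCatch(solve(Bmat, rhs), error = function(e) NULL)
      if (is.null(xB))
        return(list(ok = FALSE, reason = "singular"))
      xval[basis] <- xB

      y <- solve(t(Bmat), cost[basis])
      zN <- cost[nonbasic] - as.vector(crossprod(Aext[, nonbasic, drop = FALSE], y))
      movable <- (ube[nonbasic] - lbe[nonbasic]) > tol
      enter_ok <- movable &
        ((nb_at_lb[nonbasic] & zN > tol) | (!nb_at_lb[nonbasic] & zN < -tol))
      if (!any(enter_ok)) {
        return(list(ok = TRUE, basis = basis, nb_at_lb = nb_at_lb,
                    x = xval, iterations = it))
      }
      cand <- nonbasic[enter_ok]
      e <- if (bland) min(cand) else cand[which.max(abs(zN[enter_ok]))]
      up <- nb_at_lb[e]  # entering variable moves up from lb, else down from ub

      d <- solve(Bmat, Aext[, e])
      if (!up) d <- -d  # normalize: basic values change by -d * t, t >= 0

      t_max <- ube[e] - lbe[e]
      leave <- 0L  # 0 => bound flip
      for (k in seq_len(m)) {
        bi <- basis[k]
        if (d[k] > tol) {
          tk <- (xval[bi] - lbe[bi]) / d[k]
        } else if (d[k] < -tol) {
          tk <- (ube[bi] - xval[bi]) / (-d[k])
        } else next
        if (tk < t_max - 1e-12 ||
            (leave != 0L && tk < t_max + 1e-12 && bland && basis[k] < basis[leave])) {
          t_max <- max(tk, 0)
          leave <- k
        }
      }
      if (!is.finite(t_max))
        return(list(ok = FALSE, reason = "unbounded"))
      if (t_max <= tol) degen_run <- degen_run + 1L else degen_run <- 0L
      if (degen_run > 40L) bland <- TRUE

      if (leave == 0L) {
        nb_at_lb[e] <- !nb_at_lb[e]  # bound flip, basis unchanged
      } else {
        out <- basis[leave]
        ## leaving variable settles at the bound it ran into
        nb_at_lb[out] <- if (d[leave] > 0) TRUE else FALSE
        basis[leave] <- e
      }
    }
    list(ok = FALSE, reason = "maxit")
  }

  ## phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(cost1, basis, nb_at_lb, lbe, ube)
  if (!p1$ok) {
    st <- if (identical(p1$reason, "maxit")) "maxit" else "infeasible"
    return(list(status = st, x = rep(NA_real_, n), objective = NA_real_))
  }
  art_sum <- sum(p1$x[(n + 1L):ntot])
  if (art_sum > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))

  ## phase 2: clamp artificials and optimize the true objective
  ube[(n + 1L):ntot] <- 0
  cost2 <- c(cc, rep(0, m))
  p2 <- run_phase(cost2, p1$basis, p1$nb_at_lb, lbe, ube)
  if (!p2$ok) {
    st <- if (identical(p2$reason, "maxit")) "maxit" else "infeasible"
    return(list(status = st, x = rep(NA_real_, n), objective = NA_real_))
  }
  x <- p2$x[seq_len(n)]
  ## snap tiny bound violations from roundoff
  x <- pmin(pmax(x, lb), ub)
  objective <- sum(obj * x)
  list(status = "optimal", x = x, objective = objective)
}

#' Enumerate vertices of a flux polytope by brute force
#'
#' Independent oracle for testing: enumerates candidate basic solutions of
#' \code{\{v : S v = 0, lb <= v <= ub\}} by fixing every subset of
#' \code{n - rank(S)} variables at each combination of bounds and solving the
#' remaining square system. Only intended for networks with at most ~8
#' reactions.
#'
#' @param S stoichiometric matrix.
#' @param lb,ub bounds.
#' @param tol feasibility tolerance.
#' @return matrix with one vertex per row (possibly with duplicates removed).
#' @keywords internal
enumerate_vertices <- function(S, lb, ub, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (n > 12) stop("vertex enumeration is restricted to small networks")
  qr_S <- qr(S)
  rk <- qr_S$rank
  nfree <- n - rk
  verts <- list()
  fix_sets <- utils::combn(n, nfree, simplify = FALSE)
  if (nfree == 0) fix_sets <- list(integer(0))
  for (fx in fix_sets) {
    rest <- setdiff(seq_len(n), fx)
    Srest <- S[, rest, drop = FALSE]
    if (qr(Srest)$rank < length(rest)) next
    grid <- if (length(fx))
      expand.grid(rep(list(c(FALSE, TRUE)), length(fx)))
    else
      data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      if (length(fx)) {
        use_ub <- as.logical(grid[g, ])
        v[fx] <- ifelse(use_ub, ub[fx], lb[fx])
      }
      rhs <- -as.vector(S[, fx, drop = FALSE] %*% v[fx])
      sol <- tryCatch(qr.solve(Srest, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      v[rest] <- sol
      if (max(abs(S %*% v)) > 1e-7) next
      if (all(v >= lb - tol & v <= ub + tol))
        verts[[length(verts) + 1L]] <- pmin(pmax(v, lb), ub)
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 7)), , drop = FALSE]
}
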