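# Dense two-phase simplex for the small linear programs that arise in
# constraint-based modelling of toy-to-moderate metabolic networks.
#
# The package solves many tiny LPs (FBA, flux envelopes, ROOM relaxations)
# whose matrices have a few dozen rows; a dense tableau with Bland's
# anti-cycling rule is exact enough and guarantees termination on the
# heavily degenerate problems metabolic stoichiometry produces.

# Bounds beyond this magnitude are treated as unbounded directions and
# clamped; COBRA-style models use +/-1000 (occasionally 999999) as "infinity".
.BK_BIG_BOUND <- 1e6

#' Solve a linear program
#'
#' Minimizes (or maximizes) `obj' x` subject to row constraints
#' `A x (sense) b` and variable bounds `lb <= x <= ub`. This is the solver
#' backend used by all flux-balance and ROOM computations in the package.
#'
#' @param obj numeric objective coefficients, one per variable.
#' @param A constraint matrix (may be `NULL` for a box-only problem).
#' @param b right-hand sides, one per row of `A`.
#' @param sense character vector per row: `"="`, `"<="` or `">="`.
#' @param lb,ub variable bounds; non-finite entries are clamped to
#'   `+/-1e6` (the conventional "unbounded" magnitude in COBRA models).
#' @param maximize maximize instead of minimize.
#' @param tol pivot tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (primal solution, `NA` unless optimal) and
#'   `objective` (on the original maximize/minimize scale).
#' @keywords internal
solve_lp <- function(obj, A = NULL, b = NULL, sense = NULL,
                     lb, ub, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  if (is.null(A)) {
    A <- matrix(0, 0L, n)
    b <- numeric(0)
    sense <- character(0)
  }
  A <- as.matrix(A)
  stopifnot(ncol(A) == n, length(b) == nrow(A), length(sense) == nrow(A),
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  lb <- pmax(lb, -.BK_BIG_BOUND)
  ub <- pmin(ub, .BK_BIG_BOUND)
  cc <- if (maximize) -obj else obj

  # >= rows become <= rows
  ge <- sense == ">="
  if (any(ge)) {
    A[ge, ] <- -A[ge, , drop = FALSE]
    b[ge] <- -b[ge]
    sense[ge] <- "<="
  }
  ineq <- sense == "<="

  # shift x = lb + z, 0 <= z <= u; drop variables fixed by their bounds
  u <- ub - lb
  b2 <- b - as.vector(A %*% lb)
  keep <- which(u > 1e-12)
  nk <- length(keep)
  Ak <- A[, keep, drop = FALSE]
  uk <- u[keep]
  ck <- cc[keep]

  m_eq <- nrow(A)
  n_sl <- sum(ineq)
  # columns: structural z | inequality slacks | bound-row slacks | artificials
  ncols <- nk + n_sl + nk
  nrows <- m_eq + nk
  M <- matrix(0, nrows, ncols)
  rhs <- numeric(nrows)
  if (m_eq > 0) {
    M[seq_len(m_eq), seq_len(nk)] <- Ak
    rhs[seq_len(m_eq)] <- b2
    if (n_sl > 0) {
      sl_rows <- which(ineq)
      for (k in seq_len(n_sl)) M[sl_rows[k], nk + k] <- 1
    }
  }
  # upper-bound rows z_i + s_i = u_i
  if (nk > 0) {
    for (i in seq_len(nk)) {
      M[m_eq + i, i] <- 1
      M[m_eq + i, nk + n_sl + i] <- 1
      rhs[m_eq + i] <- uk[i]
    }
  }
  neg <- rhs < 0
  if (any(neg)) {
    M[neg, ] <- -M[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
  }
  # artificial columns, one per row
  M <- cbind(M, diag(nrows))
  art <- ncols + seq_len(nrows)
  basis <- art
  total <- ncols + nrows

  cost1 <- c(rep(0, ncols), rep(1, nrows))
  excl <- rep(FALSE, total)
  r1 <- .bk_simplex(M, rhs, basis, cost1, excl, tol)
  if (r1$status != "optimal") {
    return(list(status = r1$status, x = rep(NA_real_, n), objective = NA_real_))
  }
  p1 <- sum(cost1[r1$basis] * r1$rhs)
  if (p1 > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  M <- r1$M; rhs <- r1$rhs; basis <- r1$basis

  # pivot artificials out of the basis; drop rows that prove redundant
  drop_rows <- integer(0)
  for (i in seq_along(basis)) {
    if (basis[i] %in% art) {
      cand <- which(abs(M[i, seq_len(ncols)]) > 1e-8)
      if (length(cand)) {
        j <- cand[1]
        piv <- M[i, j]
        rowi <- M[i, ] / piv; rhi <- rhs[i] / piv
        colj <- M[, j]; colj[i] <- 0
        M <- M - outer(colj, rowi); rhs <- rhs - colj * rhi
        M[i, ] <- rowi; rhs[i] <- rhi
        basis[i] <- j
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
  }
  if (length(drop_rows)) {
    M <- M[-drop_rows, , drop = FALSE]
    rhs <- rhs[-drop_rows]
    basis <- basis[-drop_rows]
  }
  excl[art] <- TRUE

  cost2 <- c(ck, rep(0, n_sl + nk), rep(0, nrows))
  r2 <- .bk_simplex(M, rhs, basis, cost2, excl, tol)
  if (r2$status != "optimal") {
    return(list(status = r2$status, x = rep(NA_real_, n), objective = NA_real_))
  }
  zval <- numeric(ncols)
  zval[r2$basis] <- r2$rhs
  x <- lb
  x[keep] <- lb[keep] + zval[seq_len(nk)]
  objective <- sum(obj * x)
  list(status = "optimal", x = x, objective = objective)
}

# Tableau simplex core. M/rhs are kept in canonical form with respect to
# `basis`; Bland's rule (lowest eligible index in, lowest basis index out on
# ratio ties) guarantees finite termination under degeneracy.
.bk_simplex <- function(M, rhs, basis, cost, excl, tol, maxit = 100000L) {
  ncolA <- ncol(M)
  red <- cost - as.vector(cost[basis] %*% M)
  red[basis] <- 0
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) stop("simplex iteration limit reached")
    cand <- which(red < -tol & !excl)
    if (!length(cand)) break
    j <- cand[1]
    col <- M[, j]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", M = M, rhs = rhs, basis = basis))
    }
    ratios <- rhs[pos] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + 1e-9]
    i <- ties[which.min(basis[ties])]
    piv <- M[i, j]
    rowi <- M[i, ] / piv; rhi <- rhs[i] / piv
    colj <- col; colj[i] <- 0
    M <- M - outer(colj, rowi)
    rhs <- rhs - colj * rhi
    rhs[rhs < 0 & rhs > -1e-11] <- 0
    M[i, ] <- rowi; rhs[i] <- rhi
    red <- red - red[j] * rowi
    red[j] <- 0
    basis[i] <- j
  }
  list(status = "optimal", M = M, rhs = rhs, basis = basis, red = red)
}
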