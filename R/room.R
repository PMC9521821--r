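# Regulatory on/off minimization (ROOM): a mixed-integer linear program
# that predicts the flux distribution of a knockout mutant by minimizing
# the NUMBER of reactions whose flux changes significantly relative to a
# wild-type reference w. Solved by branch and bound on the built-in
# simplex; per-reaction big-M coefficients are derived from the model's
# own flux bounds, so no global M constant appears.

#' ROOM parameters
#'
#' @param delta relative significance threshold (dimensionless). A flux
#'   change counts as significant when it leaves
#'   `[w - delta|w| - epsilon, w + delta|w| + epsilon]`.
#' @param epsilon absolute significance threshold (mmol gDW^-1 hr^-1);
#'   keeps the window non-degenerate around zero fluxes.
#' @param solver_time_limit wall-clock budget per MILP, seconds.
#' @param relaxed solve only the LP relaxation of the binaries.
#' @return an object of class `room_parameters`.
#' @export
room_parameters <- function(delta = 0.03, epsilon = 0.001,
                            solver_time_limit = 60, relaxed = FALSE) {
  stopifnot(delta >= 0, epsilon >= 0, solver_time_limit > 0)
  structure(list(delta = delta, epsilon = epsilon,
                 solver_time_limit = solver_time_limit,
                 relaxed = isTRUE(relaxed)),
            class = "room_parameters")
}

#' Significance thresholds around the wild-type flux vector
#'
#' `w_u = w + delta*|w| + epsilon`, `w_l = w - delta*|w| - epsilon`.
#' A mutant flux inside `[w_l, w_u]` is an insignificant change (its binary
#' indicator may stay 0); outside, the indicator is forced to 1.
#'
#' @param w wild-type flux vector (numeric, or a `flux_distribution`).
#' @param params a [room_parameters()].
#' @return list with numeric vectors `w_u` and `w_l`.
#' @export
significance_bounds <- function(w, params = room_parameters()) {
  if (inherits(w, "flux_distribution")) w <- w$v
  w <- as.numeric(w)
  half <- params$delta * abs(w) + params$epsilon
  list(w_u = w + half, w_l = w - half)
}

#' Solve the ROOM mixed-integer program for a knockout mutant
#'
#' Minimizes the count of significant flux changes subject to steady-state
#' mass balance, flux bounds, zero flux through every knocked-out reaction,
#' and the indicator constraints
#' `v_i - y_i (v_max_i - w_u_i) <= w_u_i`,
#' `v_i - y_i (v_min_i - w_l_i) >= w_l_i`.
#' With `y_i = 0` these pin `v_i` inside the significance window; with
#' `y_i = 1` they relax to the plain flux bounds.
#'
#' @param model a [metabolic_model()].
#' @param knockouts a [knockout_set()], character vector of reaction ids,
#'   or `NULL` for the unperturbed model.
#' @param w wild-type reference (numeric vector over reactions, or a
#'   `flux_distribution` from [wild_type_reference()]).
#' @param params a [room_parameters()].
#' @return an object of class `room_result`: `v` (mutant fluxes), `y`
#'   (0/1 change indicators), `objective` (number of significant changes),
#'   `growth`, `production` (fluxes of the biomass and target reactions in
#'   `v`), and `status` (`"optimal"`, `"infeasible"`, or `"time_limit"`
#'   with the best incumbent if one was found).
#' @export
solve_room <- function(model, knockouts = NULL, w, params = room_parameters()) {
  if (inherits(w, "flux_distribution")) w <- w$v
  w <- as.numeric(w)
  n <- length(model$reaction_ids)
  if (length(w) != n)
    stop("wild-type vector length ", length(w),
         " does not match reaction count ", n)
  mod <- .bk_apply_knockouts(model, knockouts)
  sb <- significance_bounds(w, params)
  wu <- sb$w_u; wl <- sb$w_l
  lb <- unname(mod$lower_bounds); ub <- unname(mod$upper_bounds)
  mS <- nrow(mod$S)

  # variables: v (1..n), y (n+1..2n)
  nv <- 2L * n
  obj <- c(rep(0, n), rep(1, n))
  A <- matrix(0, mS + 2L * n, nv)
  b <- numeric(mS + 2L * n)
  sense <- character(mS + 2L * n)
  A[seq_len(mS), seq_len(n)] <- mod$S
  sense[seq_len(mS)] <- "="
  for (i in seq_len(n)) {
    r1 <- mS + i
    A[r1, i] <- 1
    A[r1, n + i] <- -(ub[i] - wu[i])
    b[r1] <- wu[i]
    sense[r1] <- "<="
    r2 <- mS + n + i
    A[r2, i] <- 1
    A[r2, n + i] <- -(lb[i] - wl[i])
    b[r2] <- wl[i]
    sense[r2] <- ">="
  }
  var_lb <- c(lb, rep(0, n))
  var_ub <- c(ub, rep(1, n))

  relax <- function(fix0, fix1) {
    l <- var_lb; u <- var_ub
    if (length(fix1)) l[n + fix1] <- 1
    if (length(fix0)) u[n + fix0] <- 0
    solve_lp(obj, A, b, sense, l, u, maximize = FALSE)
  }

  finish <- function(x, count, status) {
    v <- x[seq_len(n)]
    y <- as.integer(round(x[n + seq_len(n)]))
    gi <- match(mod$biomass_reaction, mod$reaction_ids)
    ti <- match(mod$target_exchange, mod$reaction_ids)
    structure(list(
      v = stats::setNames(v, mod$reaction_ids),
      y = stats::setNames(y, mod$reaction_ids),
      objective = count,
      growth = if (is.na(gi)) NA_real_ else v[gi],
      production = if (is.na(ti)) NA_real_ else v[ti],
      status = status
    ), class = "room_result")
  }

  if (params$relaxed) {
    sol <- relax(integer(0), integer(0))
    if (sol$status != "optimal")
      return(structure(list(v = NULL, y = NULL, objective = NA_real_,
                            growth = NA_real_, production = NA_real_,
                            status = sol$status), class = "room_result"))
    res <- finish(sol$x, sol$objective, "optimal")
    res$y <- sol$x[n + seq_len(n)]  # keep fractional indicators
    res$objective <- sol$objective
    return(res)
  }

  # warm incumbent: any feasible mutant flux vector with indicators set
  # wherever it leaves the significance window
  fba <- solve_fba(mod, objective = mod$biomass_reaction)
  if (fba$status != "optimal") {
    return(structure(list(v = NULL, y = NULL, objective = NA_real_,
                          growth = NA_real_, production = NA_real_,
                          status = "infeasible"), class = "room_result"))
  }
  v0 <- unname(fba$v)
  y0 <- as.numeric(v0 < wl - 1e-9 | v0 > wu + 1e-9)
  best_x <- c(v0, y0)
  best_count <- sum(y0)
  proven <- FALSE

  t_start <- proc.time()[["elapsed"]]
  timed_out <- FALSE
  stack <- list(list(fix0 = integer(0), fix1 = integer(0)))
  while (length(stack)) {
    if (proc.time()[["elapsed"]] - t_start > params$solver_time_limit) {
      timed_out <- TRUE
      break
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sol <- relax(node$fix0, node$fix1)
    if (sol$status != "optimal") next
    lbnd <- ceiling(sol$objective - 1e-6)
    if (lbnd >= best_count) next
    yv <- sol$x[n + seq_len(n)]
    frac <- abs(yv - round(yv))
    if (max(frac) < 1e-6) {
      cnt <- sum(round(yv))
      if (cnt < best_count) {
        best_count <- cnt
        best_x <- sol$x
      }
      next
    }
    j <- which.max(frac)
    stack[[length(stack) + 1L]] <- list(fix0 = node$fix0,
                                        fix1 = c(node$fix1, j))
    stack[[length(stack) + 1L]] <- list(fix0 = c(node$fix0, j),
                                        fix1 = node$fix1)
  }
  if (!timed_out) proven <- TRUE
  finish(best_x, best_count, if (proven) "optimal" else "time_limit")
}

#' @export
print.room_result <- function(x, ...) {
  cat("ROOM result (", x$status, ")\n", sep = "")
  cat("  significant flux changes: ", x$objective, "\n", sep = "")
  cat("  growth:     ", format(x$growth), " h^-1\n", sep = "")
  cat("  production: ", format(x$production), " mmol gDW^-1 hr^-1\n", sep = "")
  invisible(x)
}

#' Mutant viability filter
#'
#' A knockout mutant is considered viable when the ROOM solve was optimal,
#' its predicted growth exceeds 0.1 h^-1 (cell survival), and its predicted
#' production exceeds -1e-3 mmol gDW^-1 hr^-1 (guards against counting an
#' insignificant or negative improvement). Non-viable candidates receive
#' fitness -Inf in the search.
#'
#' @param result a `room_result`.
#' @param growth_min,production_floor the two thresholds.
#' @return `TRUE`/`FALSE`; when `FALSE`, the reason is attached as
#'   attribute `"reason"`.
#' @export
is_viable <- function(result, growth_min = 0.1, production_floor = -1e-3) {
  if (!identical(result$status, "optimal")) {
    return(structure(FALSE, reason = paste0("solver status: ", result$status)))
  }
  if (!is.finite(result$growth) || result$growth <= growth_min) {
    return(structure(FALSE, reason = "growth at or below 0.1 h^-1"))
  }
  if (!is.finite(result$production) || result$production <= production_floor) {
    return(structure(FALSE, reason = "production at or below -1e-3"))
  }
  TRUE
}
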