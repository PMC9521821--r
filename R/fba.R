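# Flux balance analysis: LP over the steady-state flux cone, the
# parsimonious wild-type reference used by ROOM, and the deterministic
# fixed-knockout production evaluator used for post-hoc validation.

new_flux_distribution <- function(v, objective_value, status, reaction_ids) {
  structure(list(
    v = stats::setNames(as.numeric(v), reaction_ids),
    objective_value = objective_value,
    status = status
  ), class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Flux distribution (", x$status, "), objective = ",
      format(x$objective_value), "\n", sep = "")
  nz <- x$v[abs(x$v) > 1e-9]
  if (length(nz)) {
    cat("  non-zero fluxes:\n")
    for (i in seq_along(nz))
      cat(sprintf("    %-14s %10.4f\n", names(nz)[i], nz[i]))
  }
  invisible(x)
}

# Apply knockouts by clamping both bounds to zero (columns are never
# deleted, so positional indexing stays valid).
.bk_apply_knockouts <- function(model, knockouts) {
  if (is.null(knockouts)) return(model)
  rxns <- if (inherits(knockouts, "knockout_set")) knockouts$reactions
          else as.character(knockouts)
  unknown <- setdiff(rxns, model$reaction_ids)
  if (length(unknown))
    stop("knockout of unknown reaction(s): ", paste(unknown, collapse = ", "))
  model$lower_bounds[rxns] <- 0
  model$upper_bounds[rxns] <- 0
  model
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to steady-state
#' mass balance `S v = 0` and flux bounds, with the reactions of `knockouts`
#' clamped to zero.
#'
#' @param model a [metabolic_model()].
#' @param objective reaction identifier to optimize (default: the model's
#'   biomass reaction).
#' @param knockouts a [knockout_set()], character vector of reaction ids,
#'   or `NULL`.
#' @param maximize direction of optimization.
#' @return a `flux_distribution` with `status` `"optimal"`, `"infeasible"`
#'   or `"unbounded"`; infeasibility is reported in the status, never as an
#'   error.
#' @export
solve_fba <- function(model, objective = model$biomass_reaction,
                      knockouts = NULL, maximize = TRUE) {
  if (is.na(objective) || !objective %in% model$reaction_ids)
    stop("objective reaction '", objective, "' not in model")
  mod <- .bk_apply_knockouts(model, knockouts)
  n <- length(mod$reaction_ids)
  obj <- numeric(n)
  obj[match(objective, mod$reaction_ids)] <- 1
  sol <- solve_lp(obj, mod$S, rep(0, nrow(mod$S)), rep("=", nrow(mod$S)),
                  mod$lower_bounds, mod$upper_bounds, maximize = maximize)
  new_flux_distribution(sol$x, sol$objective, sol$status, mod$reaction_ids)
}

# Minimize the sum of absolute fluxes with one reaction fixed at a value
# (parsimonious step). Variables are split v = p - q, p,q >= 0.
.bk_pfba <- function(model, fix_rxn, fix_val) {
  n <- length(model$reaction_ids)
  lb <- model$lower_bounds; ub <- model$upper_bounds
  k <- match(fix_rxn, model$reaction_ids)
  lb[k] <- fix_val; ub[k] <- fix_val
  p_lb <- pmax(0, lb); p_ub <- pmax(0, ub)
  q_lb <- pmax(0, -ub); q_ub <- pmax(0, -lb)
  A <- cbind(model$S, -model$S)
  sol <- solve_lp(rep(1, 2 * n), A, rep(0, nrow(A)), rep("=", nrow(A)),
                  c(p_lb, q_lb), c(p_ub, q_ub), maximize = FALSE)
  if (sol$status != "optimal") return(NULL)
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  new_flux_distribution(v, fix_val, "optimal", model$reaction_ids)
}

#' Parsimonious wild-type reference flux distribution
#'
#' The wild-type vector `w` that ROOM measures flux changes against. FBA
#' optima are typically degenerate, so the reference is pinned down by a
#' second LP: biomass is fixed at its optimum and the sum of absolute
#' fluxes is minimized (parsimonious FBA). Repeated calls return identical
#' vectors, which makes ROOM scores reproducible.
#'
#' @param model a feasible [metabolic_model()] with a biomass reaction.
#' @return a `flux_distribution`; errors if the model is infeasible (a
#'   wild type must exist).
#' @export
wild_type_reference <- function(model) {
  fba <- solve_fba(model)
  if (fba$status != "optimal")
    stop("model has no feasible wild type (FBA status: ", fba$status, ")")
  w <- .bk_pfba(model, model$biomass_reaction, fba$objective_value)
  if (is.null(w))
    stop("parsimonious minimization failed at fixed optimal biomass")
  w$objective_value <- fba$objective_value
  w
}

#' Growth and production envelope under a fixed knockout set
#'
#' The deterministic knockout evaluator: maximizes biomass under the
#' knockouts, then fixes biomass at that optimum and computes the minimum
#' and maximum attainable target-exchange flux (two further LPs). The
#' minimum is the growth-coupled production guarantee used to validate
#' knockout lists.
#'
#' @param model a [metabolic_model()] with biomass and target set.
#' @param knockouts a [knockout_set()], character vector, or `NULL`.
#' @return list with `growth`, `production_min`, `production_max`,
#'   `status`, and `flagged` (`TRUE` when the mutant was infeasible and the
#'   triple was zeroed).
#' @export
production_at_optimal_growth <- function(model, knockouts = NULL) {
  if (is.na(model$target_exchange))
    stop("model has no target exchange set")
  mod <- .bk_apply_knockouts(model, knockouts)
  fba <- solve_fba(mod)
  if (fba$status != "optimal" || fba$objective_value <= 1e-12) {
    return(list(growth = 0, production_min = 0, production_max = 0,
                status = fba$status, flagged = TRUE))
  }
  growth <- fba$objective_value
  k <- match(mod$biomass_reaction, mod$reaction_ids)
  mod$lower_bounds[k] <- growth
  mod$upper_bounds[k] <- growth
  pmin_ <- solve_fba(mod, objective = mod$target_exchange, maximize = FALSE)
  pmax_ <- solve_fba(mod, objective = mod$target_exchange, maximize = TRUE)
  if (pmin_$status != "optimal" || pmax_$status != "optimal") {
    return(list(growth = growth, production_min = 0, production_max = 0,
                status = "infeasible", flagged = TRUE))
  }
  list(growth = growth,
       production_min = pmin_$objective_value,
       production_max = pmax_$objective_value,
       status = "optimal", flagged = FALSE)
}
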