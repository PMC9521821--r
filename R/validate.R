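# Post-hoc validation of a knockout list against the independent
# deterministic evaluator: a list is "valid" when the production rate the
# search reported agrees with the growth-coupled minimum production of the
# fixed-knockout mutant to within an absolute tolerance (default 0.001
# mmol gDW^-1 hr^-1).

#' Validate a knockout list against the deterministic evaluator
#'
#' Recomputes the growth-coupled minimum production of the mutant with
#' [production_at_optimal_growth()] and compares it with the production
#' rate the optimizer reported for the same knockout set.
#'
#' @param model a [metabolic_model()].
#' @param knockout a [knockout_set()] or character vector of reaction ids.
#' @param reported_production the production rate reported by the search for
#'   this knockout set (a candidate's fitness).
#' @param tol absolute tolerance (mmol gDW^-1 hr^-1).
#' @return an object of class `validation_record`: `knockout`,
#'   `reported_production`, `evaluator_production`, `abs_difference`,
#'   `valid`, and `solver_status_code` (1 = optimal).
#' @export
validate_knockout <- function(model, knockout, reported_production,
                              tol = 0.001) {
  ks <- if (inherits(knockout, "knockout_set")) knockout
        else knockout_reactions(model, knockout)
  env <- production_at_optimal_growth(
    model, if (length(ks$reactions)) ks else NULL)
  code <- if (identical(env$status, "optimal") && !env$flagged) 1L else 0L
  diff <- abs(reported_production - env$production_min)
  structure(list(
    knockout = ks,
    reported_production = reported_production,
    evaluator_production = env$production_min,
    evaluator_growth = env$growth,
    abs_difference = diff,
    valid = code == 1L && is.finite(diff) && diff < tol,
    solver_status_code = code
  ), class = "validation_record")
}

#' @export
print.validation_record <- function(x, ...) {
  cat("Validation of knockout {",
      paste(x$knockout$reactions, collapse = ", "), "}\n", sep = "")
  cat("  search production:    ", format(x$reported_production), "\n", sep = "")
  cat("  evaluator production: ", format(x$evaluator_production), "\n",
      sep = "")
  cat("  |difference|:         ", format(x$abs_difference), "\n", sep = "")
  cat("  valid: ", x$valid, " (status code ", x$solver_status_code, ")\n",
      sep = "")
  invisible(x)
}
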