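# Exhaustive enumeration oracles over small knockout spaces. These exist
# so that the stochastic search can be checked against ground truth on
# fixtures, and they share the tie-breaking of the Bees Algorithm
# (fitness, then growth, then lexicographically smallest set).

#' Brute-force knockout table (production envelope per subset)
#'
#' Evaluates every reaction knockout set up to `max_size` with the
#' deterministic envelope evaluator [production_at_optimal_growth()].
#'
#' @param model a [metabolic_model()].
#' @param max_size largest subset size enumerated.
#' @param reactions candidate reactions (default: all).
#' @return data frame with columns `knockout` (canonical `"a|b"` key),
#'   `size`, `growth`, `production` (growth-coupled minimum) and
#'   `production_max`.
#' @export
brute_force_table <- function(model, max_size = 3,
                              reactions = model$reaction_ids) {
  .bk_guard_enumeration(length(reactions), max_size)
  subsets <- .bk_all_subsets(reactions, max_size)
  rows <- lapply(subsets, function(s) {
    env <- production_at_optimal_growth(
      model, if (length(s)) knockout_reactions(model, s) else NULL)
    data.frame(knockout = .bk_ko_key(s), size = length(s),
               growth = env$growth, production = env$production_min,
               production_max = env$production_max,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Brute-force optimal knockout set
#'
#' Exhaustively scores every knockout set of size up to `max_knockout`
#' under the same fitness definition and viability filters as the Bees
#' Algorithm, and returns the argmax with the search's own deterministic
#' tie-breaking.
#'
#' @param model a [metabolic_model()].
#' @param max_knockout largest set size (subset enumeration is guarded at
#'   1e5 sets; shrink the fixture if exceeded).
#' @param evaluator `"room"` scores through the full ROOM pipeline (the
#'   search's fitness); `"envelope"` scores by the growth-coupled minimum
#'   production alone, as an independent LP-per-subset check.
#' @param w wild-type reference (computed if omitted; only used by the
#'   `"room"` evaluator).
#' @param params [room_parameters()] for the `"room"` evaluator.
#' @return list with `best_set` (a [knockout_set()]), `best_production`,
#'   `best_growth`, and the full `table` (data frame, one row per set).
#' @export
brute_force_optimum <- function(model, max_knockout,
                                evaluator = c("room", "envelope"),
                                w = NULL, params = room_parameters()) {
  evaluator <- match.arg(evaluator)
  .bk_guard_enumeration(length(model$reaction_ids), max_knockout)
  if (evaluator == "room" && is.null(w)) w <- wild_type_reference(model)
  subsets <- .bk_all_subsets(model$reaction_ids, max_knockout)
  best <- NULL
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    if (evaluator == "room") {
      sc <- score_knockout(model, s, w, params)
      cand <- list(knockout = sort(s), fitness = sc$fitness,
                   growth = sc$growth, production = sc$fitness)
      rows[[i]] <- data.frame(knockout = .bk_ko_key(s), size = length(s),
                              fitness = sc$fitness, growth = sc$growth,
                              viable = sc$viable, stringsAsFactors = FALSE)
    } else {
      env <- production_at_optimal_growth(
        model, if (length(s)) knockout_reactions(model, s) else NULL)
      viable <- !env$flagged && env$growth > 0.1 &&
        env$production_min > -1e-3
      fit <- if (viable) env$production_min else -Inf
      cand <- list(knockout = sort(s), fitness = fit,
                   growth = env$growth, production = fit)
      rows[[i]] <- data.frame(knockout = .bk_ko_key(s), size = length(s),
                              fitness = fit, growth = env$growth,
                              viable = viable, stringsAsFactors = FALSE)
    }
    if (is.null(best) || .bk_candidate_better(cand, best)) best <- cand
  }
  list(best_set = knockout_set(reactions = best$knockout),
       best_production = best$fitness,
       best_growth = best$growth,
       table = do.call(rbind, rows))
}

.bk_guard_enumeration <- function(n, k, limit = 1e5) {
  total <- sum(vapply(0:min(k, n), function(j) choose(n, j), numeric(1)))
  if (total > limit)
    stop("enumeration of ", format(total), " knockout sets exceeds the ",
         format(limit), " guard; shrink the fixture or max_knockout")
  invisible(total)
}

.bk_all_subsets <- function(ids, max_size) {
  out <- list(character(0))
  for (k in seq_len(min(max_size, length(ids)))) {
    cmb <- utils::combn(ids, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# Deterministic candidate ordering shared by the search and the oracle:
# higher fitness first, then higher growth, then the lexicographically
# smallest canonical knockout key.
.bk_candidate_better <- function(a, b) {
  fa <- if (is.finite(a$fitness)) a$fitness else -Inf
  fb <- if (is.finite(b$fitness)) b$fitness else -Inf
  if (fa != fb) return(fa > fb)
  ga <- if (is.finite(a$growth %||% NA_real_)) a$growth else -Inf
  gb <- if (is.finite(b$growth %||% NA_real_)) b$growth else -Inf
  if (abs(ga - gb) > 1e-12) return(ga > gb)
  ka <- .bk_ko_key(a$knockout); kb <- .bk_ko_key(b$knockout)
  ka < kb
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x[1])) y else x
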