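# The Bees Algorithm outer search: a population of binary knockout
# genotypes over the model's reaction list, scored by the ROOM pipeline,
# with elite-site neighbourhood recruitment and random scout re-assignment.

#' Bees Algorithm configuration
#'
#' Defaults follow the published parameterization of the hybrid search:
#' 30 scout bees, 20 selected sites of which 2 are elite, 4 recruits per
#' elite site and 8 per remaining selected site, bit-flip neighbourhood
#' radius 1, an oversampled random initialization pool of 2000 genotypes,
#' and 50 iterations.
#'
#' @param n scout bees (population size).
#' @param m selected sites per iteration.
#' @param e elite sites among the `m`.
#' @param nep recruited bees per elite site.
#' @param nsp recruited bees per non-elite selected site.
#' @param ngh neighbourhood radius: maximum bits flipped per recruit.
#' @param dimension size of the random initialization pool from which the
#'   `n` distinct scouts are drawn.
#' @param imax iterations (termination condition).
#' @param max_knockout largest allowed knockout-set size (1-5 in the
#'   benchmark protocol; any candidate is repaired down to this size).
#' @param seed RNG seed; every stochastic choice in a run flows from it.
#' @param validation_tol absolute production-rate tolerance of the post-hoc
#'   validation (mmol gDW^-1 hr^-1).
#' @param top_k number of distinct knockout lists retained in the report.
#' @param delta,epsilon ROOM significance thresholds (see
#'   [room_parameters()]).
#' @param time_limit ROOM MILP time limit per evaluation, seconds.
#' @return an object of class `ba_config`.
#' @export
ba_config <- function(n = 30, m = 20, e = 2, nep = 4, nsp = 8, ngh = 1,
                      dimension = 2000, imax = 50, max_knockout = 2,
                      seed = 1, validation_tol = 0.001, top_k = 3,
                      delta = 0.03, epsilon = 0.001, time_limit = 60) {
  stopifnot(e >= 1, e <= m, m <= n, nep >= 1, nsp >= 1, ngh >= 1,
            imax >= 1, dimension >= n, max_knockout >= 1,
            validation_tol > 0, top_k >= 1)
  structure(list(n = as.integer(n), m = as.integer(m), e = as.integer(e),
                 nep = as.integer(nep), nsp = as.integer(nsp),
                 ngh = as.integer(ngh), dimension = as.integer(dimension),
                 imax = as.integer(imax),
                 max_knockout = as.integer(max_knockout),
                 seed = as.integer(seed), validation_tol = validation_tol,
                 top_k = as.integer(top_k), delta = delta,
                 epsilon = epsilon, time_limit = time_limit),
            class = "ba_config")
}

.bk_new_candidate <- function(presence, model) {
  list(presence = as.integer(presence),
       knockout = model$reaction_ids[presence == 0L],
       fitness = -Inf, growth = NA_real_, production = NA_real_,
       room_status = NA_character_, room_objective = NA_real_,
       viable = FALSE, evaluated = FALSE)
}

# Re-enable randomly chosen knocked-out positions until at most
# max_knockout zeros remain.
.bk_repair <- function(presence, max_knockout) {
  zeros <- which(presence == 0L)
  if (length(zeros) > max_knockout) {
    keep <- zeros[sample.int(length(zeros), max_knockout)]
    presence[setdiff(zeros, keep)] <- 1L
  }
  presence
}

.bk_random_candidate <- function(model, config) {
  nrxn <- length(model$reaction_ids)
  pres <- .bk_repair(stats::rbinom(nrxn, 1L, 0.5), config$max_knockout)
  .bk_new_candidate(pres, model)
}

# Draw `dimension` random genotypes, repair, deduplicate, and keep the
# first n distinct ones; generation continues past the pool if the pool
# held fewer than n distinct genotypes (a small model may not even admit n
# distinct repaired genotypes, in which case all of them are returned).
.bk_init_population <- function(model, config) {
  nrxn <- length(model$reaction_ids)
  if (nrxn < config$max_knockout)
    stop("model has fewer reactions (", nrxn, ") than max_knockout (",
         config$max_knockout, ")")
  seen <- new.env(parent = emptyenv())
  pop <- vector("list", config$n)
  count <- 0L
  n_space <- sum(vapply(0:config$max_knockout,
                        function(k) choose(nrxn, k), numeric(1)))
  attempts_max <- config$dimension + 200L * config$n
  attempts <- 0L
  while (count < min(config$n, n_space) && attempts < attempts_max) {
    attempts <- attempts + 1L
    cand <- .bk_random_candidate(model, config)
    key <- paste0("k:", .bk_ko_key(cand$knockout))
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      count <- count + 1L
      pop[[count]] <- cand
    }
  }
  pop[seq_len(count)]
}

#' Initialize the scout-bee population
#'
#' Deterministic given `config$seed`: generates `config$dimension` random
#' presence/absence genotypes over the reaction list, repairs each to at
#' most `max_knockout` knockouts, deduplicates, and returns the first
#' `config$n` distinct candidates.
#'
#' @param model a [metabolic_model()].
#' @param config a [ba_config()].
#' @return list of unevaluated candidates.
#' @export
init_population <- function(model, config = ba_config()) {
  .bk_with_seed(config$seed, .bk_init_population(model, config))
}

# Score a candidate through the shared ROOM pipeline, memoized on the
# canonical knockout set (the search revisits sets frequently). Only cache
# misses hit the MILP solver and are appended to the evaluation log.
score_candidate <- function(cand, ctx) {
  if (isTRUE(cand$evaluated)) return(cand)
  key <- paste0("k:", .bk_ko_key(cand$knockout))
  sc <- ctx$cache[[key]]
  if (is.null(sc)) {
    t0 <- proc.time()[["elapsed"]]
    sc <- score_knockout(ctx$model, cand$knockout, ctx$w, ctx$params)
    sc$wall_time <- proc.time()[["elapsed"]] - t0
    ctx$cache[[key]] <- sc
    ctx$log[[length(ctx$log) + 1L]] <- data.frame(
      iteration = ctx$iteration,
      knockout = .bk_ko_key(cand$knockout),
      status = sc$room_status,
      objective = sc$room_objective,
      growth = sc$growth,
      production_room = sc$production_room,
      production_min = sc$production_min,
      fitness = sc$fitness,
      viable = sc$viable,
      reason = if (is.na(sc$reason)) "" else sc$reason,
      wall_time = sc$wall_time,
      stringsAsFactors = FALSE)
  }
  cand$fitness <- sc$fitness
  cand$growth <- sc$growth
  cand$production <- sc$fitness
  cand$room_status <- sc$room_status
  cand$room_objective <- sc$room_objective
  cand$viable <- sc$viable
  cand$evaluated <- TRUE
  cand
}

.bk_neighborhood <- function(site, recruits, ctx) {
  best <- site
  nrxn <- length(site$presence)
  ngh <- ctx$config$ngh
  for (r in seq_len(recruits)) {
    nf <- if (ngh > 1L) sample.int(ngh, 1L) else 1L
    pos <- sample.int(nrxn, nf)
    pres <- site$presence
    pres[pos] <- 1L - pres[pos]
    pres <- .bk_repair(pres, ctx$config$max_knockout)
    cand <- score_candidate(.bk_new_candidate(pres, ctx$model), ctx)
    if (.bk_candidate_better(cand, best)) best <- cand
  }
  best
}

#' Neighbourhood search around one site
#'
#' Generates `recruits` neighbours of an evaluated site, each by flipping
#' up to `ngh` uniformly chosen bits of the presence genotype (followed by
#' repair to `max_knockout`), scores them, and returns the best of the
#' site and its neighbours. Ties break on higher growth, then on the
#' lexicographically smallest knockout set.
#'
#' @param site an evaluated candidate (e.g. from a scored population).
#' @param model,w,config,params the evaluation context: model, wild-type
#'   reference, [ba_config()] and [room_parameters()].
#' @param recruits number of recruited bees.
#' @param seed optional seed making the call self-contained.
#' @return the best evaluated candidate found.
#' @export
neighborhood_search <- function(site, model, w, config = ba_config(),
                                recruits = config$nep, params = NULL,
                                seed = NULL) {
  if (inherits(w, "flux_distribution")) w <- unname(w$v)
  ctx <- new.env(parent = emptyenv())
  ctx$model <- model
  ctx$w <- w
  ctx$config <- config
  ctx$params <- params %||%
    room_parameters(config$delta, config$epsilon, config$time_limit)
  ctx$cache <- new.env(parent = emptyenv())
  ctx$log <- list()
  ctx$iteration <- 0L
  site <- score_candidate(site, ctx)
  if (!is.null(seed)) .bk_with_seed(seed, .bk_neighborhood(site, recruits, ctx))
  else .bk_neighborhood(site, recruits, ctx)
}

#' Bees-Algorithm knockout search scored by ROOM
#'
#' The main optimizer. Each iteration scores the population through the
#' ROOM pipeline (memoized per distinct knockout set), sorts it by fitness,
#' selects the top `m` sites (`e` elite), improves each site by
#' neighbourhood recruitment (`nep` recruits per elite site, `nsp`
#' otherwise), and refills the colony with `n - m` fresh random scouts.
#' The run is deterministic given `config$seed`.
#'
#' @param model a [metabolic_model()] (biomass and target set, or supplied
#'   via `biomass` / `target`).
#' @param config a [ba_config()].
#' @param target,biomass optional reaction identifiers overriding the
#'   model's target exchange and biomass reaction.
#' @return an object of class `beeknock`: the best candidate found, the
#'   `top_k` distinct knockout lists with validation records, the
#'   per-iteration best-fitness trace, the full evaluation log, and the
#'   wild-type reference read-outs. See [render_report()] for file output.
#' @export
beeknock <- function(model, config = ba_config(), target = NULL,
                     biomass = NULL) {
  if (!is.null(biomass)) {
    stopifnot(biomass %in% model$reaction_ids)
    model$biomass_reaction <- biomass
  }
  if (!is.null(target)) {
    stopifnot(target %in% model$reaction_ids)
    model$target_exchange <- target
  }
  if (is.na(model$biomass_reaction))
    stop("model has no biomass reaction set")
  if (is.na(model$target_exchange))
    stop("model has no target exchange set")

  w_fd <- wild_type_reference(model)
  wt_env <- production_at_optimal_growth(model)

  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  ctx <- new.env(parent = emptyenv())
  ctx$model <- model
  ctx$w <- unname(w_fd$v)
  ctx$config <- config
  ctx$params <- room_parameters(config$delta, config$epsilon,
                                config$time_limit)
  ctx$cache <- new.env(parent = emptyenv())
  ctx$log <- list()
  ctx$iteration <- 0L

  pop <- .bk_init_population(model, config)
  global_best <- NULL
  trace <- vector("list", config$imax)

  for (it in seq_len(config$imax)) {
    ctx$iteration <- it
    pop <- lapply(pop, score_candidate, ctx = ctx)
    fit <- vapply(pop, function(c) c$fitness, numeric(1))
    grw <- vapply(pop, function(c) {
      g <- c$growth; if (is.finite(g)) g else -Inf
    }, numeric(1))
    keys <- vapply(pop, function(c) .bk_ko_key(c$knockout), character(1))
    ord <- order(-fit, -grw, keys)
    n_sites <- min(config$m, length(pop))
    reps <- vector("list", n_sites)
    for (s in seq_len(n_sites)) {
      recruits <- if (s <= config$e) config$nep else config$nsp
      reps[[s]] <- .bk_neighborhood(pop[[ord[s]]], recruits, ctx)
    }
    iter_best <- reps[[1]]
    for (s in seq_along(reps)) {
      if (.bk_candidate_better(reps[[s]], iter_best)) iter_best <- reps[[s]]
    }
    if (is.null(global_best) || .bk_candidate_better(iter_best, global_best))
      global_best <- iter_best
    trace[[it]] <- data.frame(iteration = it,
                              iteration_best = iter_best$fitness,
                              global_best = global_best$fitness)
    scouts <- lapply(seq_len(config$n - n_sites),
                     function(i) .bk_random_candidate(model, config))
    pop <- c(reps, scouts)
  }

  evaluations <- if (length(ctx$log)) do.call(rbind, ctx$log) else
    data.frame(iteration = integer(0), knockout = character(0),
               status = character(0), objective = numeric(0),
               growth = numeric(0), production_room = numeric(0),
               production_min = numeric(0), fitness = numeric(0),
               viable = logical(0), reason = character(0),
               wall_time = numeric(0))

  # distinct viable knockout lists, best first
  cache_keys <- ls(ctx$cache)
  entries <- lapply(cache_keys, function(k) ctx$cache[[k]])
  viable <- Filter(function(e) isTRUE(e$viable), entries)
  if (length(viable)) {
    vord <- order(-vapply(viable, function(e) e$fitness, numeric(1)),
                  -vapply(viable, function(e) e$growth, numeric(1)),
                  vapply(viable, function(e) .bk_ko_key(e$knockout),
                         character(1)))
    viable <- viable[vord[seq_len(min(config$top_k, length(viable)))]]
  }
  top_sets <- if (!length(viable)) NULL else
    do.call(rbind, c(lapply(seq_along(viable), function(i) {
    e <- viable[[i]]
    val <- validate_knockout(model, e$knockout,
                             reported_production = e$fitness,
                             tol = config$validation_tol)
    data.frame(rank = i,
               knockout = .bk_ko_key(e$knockout),
               genes = paste(associated_genes(model, e$knockout),
                             collapse = ";"),
               production = e$fitness,
               growth = e$growth,
               room_objective = e$room_objective,
               room_status = e$room_status,
               evaluator_production = val$evaluator_production,
               abs_difference = val$abs_difference,
               valid = val$valid,
               solver_status_code = val$solver_status_code,
               stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  if (is.null(top_sets)) {
    top_sets <- data.frame(rank = integer(0), knockout = character(0),
                           genes = character(0), production = numeric(0),
                           growth = numeric(0), room_objective = numeric(0),
                           room_status = character(0),
                           evaluator_production = numeric(0),
                           abs_difference = numeric(0), valid = logical(0),
                           solver_status_code = integer(0),
                           stringsAsFactors = FALSE)
  }

  viable_found <- is.finite(global_best$fitness)
  best <- list(
    knockout = if (viable_found) sort(global_best$knockout) else character(0),
    genes = if (viable_found)
      associated_genes(model, sort(global_best$knockout)) else character(0),
    fitness = global_best$fitness,
    production = global_best$production,
    growth = global_best$growth,
    room_objective = global_best$room_objective,
    room_status = global_best$room_status
  )

  structure(list(
    best = best,
    viable_found = viable_found,
    top_sets = top_sets,
    trace = do.call(rbind, trace),
    evaluations = evaluations,
    wild_type = list(growth = wt_env$growth,
                     production_min = wt_env$production_min,
                     production_max = wt_env$production_max),
    n_room_solves = length(cache_keys),
    model_id = model$id,
    n_reactions = length(model$reaction_ids),
    config = config
  ), class = "beeknock")
}
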