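# The single scoring pipeline shared by the Bees Algorithm and the
# brute-force oracle, so both rank knockout sets by exactly the same
# fitness definition.
#
# A candidate's fitness is the growth-coupled minimum production of the
# mutant (the pessimistic value of the production envelope at the mutant's
# optimal growth), awarded only if ROOM declares the mutant viable:
# the ROOM solve must be optimal, ROOM's predicted mutant growth must
# exceed 0.1 h^-1 and neither ROOM's predicted production nor the envelope
# minimum may fall below -1e-3 mmol gDW^-1 hr^-1. Anything else scores
# -Inf and is discarded by the search.

score_knockout <- function(model, reactions, w, params,
                           growth_min = 0.1, production_floor = -1e-3) {
  ks <- if (length(reactions)) knockout_reactions(model, reactions)
        else knockout_set()
  room <- solve_room(model, ks, w, params)
  out <- list(
    knockout = ks$reactions,
    room_status = room$status,
    room_objective = room$objective,
    growth = room$growth,
    production_room = room$production,
    production_min = NA_real_,
    fitness = -Inf,
    viable = FALSE,
    reason = NA_character_
  )
  ok <- is_viable(room, growth_min = growth_min,
                  production_floor = production_floor)
  if (!isTRUE(ok)) {
    out$reason <- attr(ok, "reason")
    return(out)
  }
  env <- production_at_optimal_growth(model, ks)
  out$production_min <- env$production_min
  if (env$flagged || env$production_min <= production_floor) {
    out$reason <- "growth-coupled production at or below -1e-3"
    return(out)
  }
  out$fitness <- env$production_min
  out$viable <- TRUE
  out
}

# Canonical cache / sort key of a reaction knockout set.
.bk_ko_key <- function(reactions) paste(sort(reactions), collapse = "|")
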