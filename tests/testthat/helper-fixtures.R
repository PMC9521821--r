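# Shared fixtures and independent oracles for the test suite.

# 7-reaction fixture: linear chain, single drain (unique optimal knockout
# at max_knockout = 1).
toy7 <- function(seed = 1, ...) {
  make_toy_network(pathway_length = 2, branches = 1, uptake = 10,
                   seed = seed, ...)
}

# 8-reaction fixture: two competing drains (optimum needs a double
# knockout).
toy8 <- function(seed = 1, ...) {
  make_toy_network(pathway_length = 2, branches = 2, uptake = 10,
                   seed = seed, ...)
}

# small Bees Algorithm configuration for desk-scale runs
small_config <- function(...) {
  defaults <- list(n = 10, m = 6, e = 2, nep = 4, nsp = 2, ngh = 1,
                   dimension = 200, imax = 10, max_knockout = 2, seed = 1)
  do.call(ba_config, utils::modifyList(defaults, list(...)))
}

# Exhaustive ROOM oracle: enumerate binary change patterns level by level
# (increasing number of changes) and return the first level at which some
# pattern admits a feasible flux vector. Independent of the branch-and-
# bound search in solve_room.
room_enum_oracle <- function(model, knockouts, w, params = room_parameters()) {
  if (inherits(w, "flux_distribution")) w <- unname(w$v)
  mod <- beeknock:::.bk_apply_knockouts(model, knockouts)
  sb <- significance_bounds(w, params)
  n <- length(mod$reaction_ids)
  lb <- unname(mod$lower_bounds); ub <- unname(mod$upper_bounds)
  S <- mod$S
  feasible_pattern <- function(changed) {
    l <- lb; u <- ub
    unchanged <- setdiff(seq_len(n), changed)
    l[unchanged] <- pmax(l[unchanged], sb$w_l[unchanged])
    u[unchanged] <- pmin(u[unchanged], sb$w_u[unchanged])
    if (any(l > u + 1e-12)) return(FALSE)
    sol <- beeknock:::solve_lp(rep(0, n), S, rep(0, nrow(S)),
                               rep("=", nrow(S)), l, u)
    sol$status == "optimal"
  }
  for (k in 0:n) {
    sets <- if (k == 0) list(integer(0)) else
      utils::combn(seq_len(n), k, simplify = FALSE)
    for (s in sets) if (feasible_pattern(s)) return(k)
  }
  NA_integer_
}

# Run a python snippet with a JSON payload on disk; returns the parsed
# JSON the snippet writes to `out_file`. Used to cross-check the LP layer
# and the model writers against scipy / cobrapy.
py_oracle <- function(code, payload = NULL) {
  in_file <- tempfile(fileext = ".json")
  out_file <- tempfile(fileext = ".json")
  if (!is.null(payload))
    jsonlite::write_json(payload, in_file, auto_unbox = TRUE, digits = NA)
  full <- paste0("import json\nIN_FILE=", deparse(in_file),
                 "\nOUT_FILE=", deparse(out_file), "\n", code)
  status <- system2("python", "-", input = full,
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python oracle failed")
  jsonlite::fromJSON(out_file, simplifyVector = TRUE)
}
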