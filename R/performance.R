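# The repeated-run performance protocol: for each maximum knockout size,
# run the optimizer several times with distinct seeds and tabulate the
# growth-rate mean and standard deviation of the final knockout list plus
# the fractions of runs with an optimal solver status and a validated
# solution.

#' Measure search performance over repeated seeded runs
#'
#' @param model a [metabolic_model()].
#' @param config a [ba_config()]; its seed anchors the per-run seeds
#'   (`seed + 997*max_knockout + run`), so the whole protocol is
#'   reproducible.
#' @param runs runs per maximum-knockout value (>= 2).
#' @param max_knockouts vector of maximum knockout sizes to profile.
#' @return a data frame of class `bk_performance` with one row per
#'   maximum-knockout value: `mean_growth`, `sd_growth`,
#'   `accuracy_optimal` and `accuracy_valid` (fractions in [0, 1]).
#'   Per-run results are attached as attribute `"runs"`.
#' @export
measure_performance <- function(model, config = ba_config(), runs = 10,
                                max_knockouts = 1:5) {
  stopifnot(runs >= 2)
  detail <- list()
  rows <- lapply(max_knockouts, function(mk) {
    growth <- numeric(runs)
    optimal <- logical(runs)
    valid <- logical(runs)
    for (r in seq_len(runs)) {
      cfg <- config
      cfg$max_knockout <- as.integer(mk)
      cfg$seed <- as.integer(config$seed + 997L * mk + r)
      res <- beeknock(model, cfg)
      growth[r] <- if (res$viable_found) res$best$growth else NA_real_
      optimal[r] <- res$viable_found &&
        identical(res$best$room_status, "optimal")
      valid[r] <- res$viable_found && nrow(res$top_sets) > 0 &&
        isTRUE(res$top_sets$valid[1])
      detail[[length(detail) + 1L]] <<- data.frame(
        max_knockout = mk, run = r, seed = cfg$seed,
        knockout = if (res$viable_found)
          paste(res$best$knockout, collapse = "|") else "",
        production = res$best$fitness, growth = growth[r],
        optimal = optimal[r], valid = valid[r], stringsAsFactors = FALSE)
    }
    data.frame(max_knockout = mk,
               runs = runs,
               mean_growth = mean(growth, na.rm = TRUE),
               sd_growth = stats::sd(growth, na.rm = TRUE),
               accuracy_optimal = mean(optimal),
               accuracy_valid = mean(valid))
  })
  out <- do.call(rbind, rows)
  attr(out, "runs") <- do.call(rbind, detail)
  class(out) <- c("bk_performance", "data.frame")
  out
}

#' @export
print.bk_performance <- function(x, ...) {
  cat("Search performance over", x$runs[1], "runs per maximum knockout\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
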