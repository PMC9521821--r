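# Rendering an optimization report to files (JSON + TSV knockout table +
# evaluation log) and reading it back, plus the print/summary/plot
# methods of the `beeknock` result object.

#' Write an optimization report to disk
#'
#' Produces three files in `dir`:
#' \describe{
#'   \item{`report.json`}{the full report (best candidate, retained
#'     knockout lists with validation, per-iteration trace, evaluation
#'     history, configuration). Wall-clock times are excluded, so the file
#'     is byte-identical across runs with the same seed.}
#'   \item{`knockout_table.tsv`}{one row per retained knockout list:
#'     knocked-out reactions, associated genes, production and growth
#'     rate, validation verdict.}
#'   \item{`evaluations.log`}{one tab-separated line per ROOM solver call:
#'     knockout set, solver status, objective (number of significant flux
#'     changes), growth, production read-outs, fitness and wall time.}
#' }
#'
#' @param report a `beeknock` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths of the files written.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "beeknock"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(json = file.path(dir, "report.json"),
             tsv = file.path(dir, "knockout_table.tsv"),
             log = file.path(dir, "evaluations.log"))

  core <- report_core(report)
  json <- jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  writeLines(json, paths[["json"]])

  tsv <- report$top_sets[, c("rank", "knockout", "genes", "production",
                             "growth", "valid")]
  names(tsv) <- c("rank", "knockout_reactions", "associated_genes",
                  "production", "growth_rate", "valid")
  utils::write.table(tsv, paths[["tsv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  utils::write.table(report$evaluations, paths[["log"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# The deterministic portion of a report (no wall times). Fitness -Inf
# marks a discarded candidate; JSON has no representation for it, so it is
# rendered as null (NA) here and in everything derived from this core.
report_core <- function(report) {
  ev <- report$evaluations
  ev$wall_time <- NULL
  ninf_na <- function(x) { x[is.infinite(x)] <- NA_real_; x }
  ev$fitness <- ninf_na(ev$fitness)
  best <- report$best
  best$fitness <- ninf_na(best$fitness)
  best$production <- ninf_na(best$production)
  tr <- report$trace
  tr$iteration_best <- ninf_na(tr$iteration_best)
  tr$global_best <- ninf_na(tr$global_best)
  list(
    model_id = report$model_id,
    n_reactions = report$n_reactions,
    viable_found = report$viable_found,
    best = best,
    wild_type = report$wild_type,
    top_sets = report$top_sets,
    trace = tr,
    evaluations = ev,
    n_room_solves = report$n_room_solves,
    config = unclass(report$config)
  )
}

#' Read a report back from its JSON rendering
#'
#' Reconstructs the deterministic portion of a `beeknock` report from
#' `report.json`; `read_report(render_report(x, dir))` returns an object
#' whose fields equal `report_core` of `x`.
#'
#' @param path path to a `report.json` (or the directory holding it).
#' @return a list with the report fields (class `beeknock_report`).
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  doc$best$knockout <- as.character(doc$best$knockout %||% character(0))
  doc$best$genes <- as.character(doc$best$genes %||% character(0))
  structure(doc, class = "beeknock_report")
}

#' @export
print.beeknock <- function(x, ...) {
  cat("Bees-Algorithm / ROOM knockout search on '", x$model_id, "'\n",
      sep = "")
  cat("  iterations: ", x$config$imax, ", seed ", x$config$seed,
      ", max knockout ", x$config$max_knockout, "\n", sep = "")
  cat("  distinct knockout sets evaluated: ", x$n_room_solves, "\n",
      sep = "")
  if (x$viable_found) {
    cat("  best knockout: {", paste(x$best$knockout, collapse = ", "),
        "}\n", sep = "")
    cat("  production: ", format(x$best$production),
        " mmol gDW^-1 hr^-1, growth: ", format(x$best$growth),
        " h^-1\n", sep = "")
  } else {
    cat("  no viable knockout candidate found\n")
  }
  invisible(x)
}

#' @export
summary.beeknock <- function(object, ...) {
  print(object)
  cat("\nWild type: growth ", format(object$wild_type$growth),
      " h^-1, growth-coupled production ",
      format(object$wild_type$production_min), "\n", sep = "")
  if (nrow(object$top_sets)) {
    cat("\nRetained knockout lists:\n")
    print.data.frame(object$top_sets[, c("rank", "knockout", "genes",
                                         "production", "growth", "valid")],
                     row.names = FALSE, digits = 6)
  }
  invisible(object)
}

#' Convergence trace of a search
#'
#' Plots the per-iteration best fitness and the running global best
#' (elitism makes the latter non-decreasing).
#'
#' @param x a `beeknock` object.
#' @param ... passed to [plot()].
#' @export
plot.beeknock <- function(x, ...) {
  tr <- x$trace
  finite <- tr$global_best[is.finite(tr$global_best)]
  ylim <- if (length(finite)) range(c(0, finite)) else c(0, 1)
  plot(tr$iteration, pmax(tr$global_best, ylim[1]), type = "s", lwd = 2,
       xlab = "iteration", ylab = "best production (mmol gDW^-1 hr^-1)",
       ylim = ylim, ...)
  points(tr$iteration, pmax(tr$iteration_best, ylim[1]), pch = 1,
         col = "grey40")
  legend("bottomright", bty = "n", lwd = c(2, NA), pch = c(NA, 1),
         col = c("black", "grey40"),
         legend = c("global best", "iteration best"))
  invisible(x)
}
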