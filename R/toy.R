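# Deterministic toy metabolic networks for testing and benchmarking the
# knockout search at desk scale. The networks are built so that the
# optimal knockout strategy is known by construction and cheap to confirm
# by brute force.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
.bk_with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a toy metabolic network with a known optimal knockout
#'
#' Builds a small self-contained model: one substrate exchange (uptake
#' `uptake` mmol gDW^-1 hr^-1), a linear catabolic chain of
#' `pathway_length` gene-associated steps whose first step also yields an
#' energy cofactor, a gene-associated synthesis route from the terminal
#' intermediate to the target product with its exchange, `branches`
#' competing overflow drains on the same intermediate, and a biomass
#' pseudo-reaction consuming intermediate plus cofactor.
#'
#' The cofactor stoichiometry caps growth below what the carbon supply
#' allows, so at maximal growth half of the intermediate is excess and
#' leaves through a drain (drains are parsimonious: one reaction versus two
#' for the product route). Consequently the wild type grows but produces
#' nothing growth-coupled, and knocking out all drains redirects the excess
#' to the target at unchanged maximal growth — at least one knockout set
#' strictly increases production by construction.
#'
#' The `seed` controls cosmetic randomization (which chain step carries a
#' two-gene enzyme complex, which drain carries an isozyme pair, drain
#' order); the same seed always yields an identical model.
#'
#' @param pathway_length number of chain reactions (>= 1).
#' @param branches number of competing drain reactions (>= 1).
#' @param uptake substrate uptake bound (mmol gDW^-1 hr^-1).
#' @param seed integer seed for the cosmetic randomization.
#' @param oracle attach the brute-force knockout table (see
#'   [brute_force_table()]) as attribute `"oracle_table"`.
#' @param oracle_max_size largest knockout-set size tabulated.
#' @return a [metabolic_model()]; with `oracle = TRUE` the attribute
#'   `"oracle_table"` holds a data frame of every reaction knockout set up
#'   to `oracle_max_size` with its growth and growth-coupled production.
#' @export
make_toy_network <- function(pathway_length = 2, branches = 1, uptake = 10,
                             seed = 1, oracle = TRUE, oracle_max_size = 3) {
  stopifnot(pathway_length >= 1, branches >= 1, uptake > 0)
  .bk_with_seed(seed, {
    complex_step <- sample.int(pathway_length, 1)
    isozyme_drain <- if (branches > 1) sample.int(branches, 1) else 0L
    drain_order <- sample.int(branches)

    chain_mets <- if (pathway_length > 1)
      paste0("I", seq_len(pathway_length - 1)) else character(0)
    mets <- c("A", chain_mets, "B", "ATP", "P")
    nm <- length(mets)
    midx <- stats::setNames(seq_len(nm), mets)

    rxn_ids <- c("EX_carbon",
                 paste0("STEP", seq_len(pathway_length)),
                 "SYNTH", "EX_target",
                 paste0("DRAIN", drain_order),
                 "BIOMASS")
    n <- length(rxn_ids)
    S <- matrix(0, nm, n, dimnames = list(mets, rxn_ids))
    lb <- stats::setNames(rep(0, n), rxn_ids)
    ub <- stats::setNames(rep(1000, n), rxn_ids)
    gpr <- stats::setNames(rep("", n), rxn_ids)

    S["A", "EX_carbon"] <- -1
    lb["EX_carbon"] <- -uptake
    ub["EX_carbon"] <- 0

    chain_nodes <- c("A", chain_mets, "B")
    for (i in seq_len(pathway_length)) {
      rx <- paste0("STEP", i)
      S[chain_nodes[i], rx] <- -1
      S[chain_nodes[i + 1], rx] <- 1
      if (i == 1) S["ATP", rx] <- 1
      gpr[rx] <- if (i == complex_step)
        sprintf("gs%da and gs%db", i, i) else sprintf("gs%d", i)
    }

    S["B", "SYNTH"] <- -1
    S["P", "SYNTH"] <- 1
    gpr["SYNTH"] <- "gt"
    S["P", "EX_target"] <- -1

    for (k in seq_len(branches)) {
      rx <- paste0("DRAIN", k)
      S["B", rx] <- -1
      gpr[rx] <- if (k == isozyme_drain)
        sprintf("gd%da or gd%db", k, k) else sprintf("gd%d", k)
    }

    # growth needs 10 B + 20 ATP per unit, but the chain yields only
    # 1 ATP per B: at uptake u, max growth is u/20 and u/2 of B is excess
    S["B", "BIOMASS"] <- -10
    S["ATP", "BIOMASS"] <- -20

    model <- metabolic_model(
      rxn_ids, mets, S, lb, ub, gpr,
      biomass_reaction = "BIOMASS", target_exchange = "EX_target",
      id = sprintf("toy_L%d_K%d_u%g_s%d", pathway_length, branches,
                   uptake, seed))
    if (oracle) {
      attr(model, "oracle_table") <-
        brute_force_table(model, max_size = oracle_max_size)
    }
    model
  })
}
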