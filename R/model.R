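# Internal representation of a constraint-based metabolic model and the
# gene-protein-reaction (GPR) boolean layer that maps gene deletions to
# disabled reactions.

#' Construct a metabolic model
#'
#' Builds the package's internal constraint-based model container: a
#' stoichiometric matrix with per-reaction flux bounds and GPR rules, plus
#' the identities of the biomass pseudo-reaction and the target exchange
#' whose flux is the production read-out. Reaction order is the order of
#' `reaction_ids` and is preserved everywhere (bee genotypes index reactions
#' by position, so the order must be stable).
#'
#' @param reaction_ids character vector of reaction identifiers (column
#'   order of `S`).
#' @param metabolite_ids character vector of metabolite identifiers (row
#'   order of `S`).
#' @param S stoichiometric matrix, metabolites x reactions.
#' @param lower_bounds,upper_bounds per-reaction flux bounds
#'   (mmol gDW^-1 hr^-1).
#' @param gpr character vector of GPR rules (`"g1 and (g2 or g3)"`), `""`
#'   for reactions with no gene association.
#' @param biomass_reaction,target_exchange reaction identifiers; may be
#'   `NA` and set later, but must be present in `reaction_ids` when given.
#' @param medium optional named numeric: exchange reaction -> uptake rate
#'   (positive number; applied as a negative lower bound).
#' @param id model identifier string.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(reaction_ids, metabolite_ids, S,
                            lower_bounds, upper_bounds, gpr = NULL,
                            biomass_reaction = NA_character_,
                            target_exchange = NA_character_,
                            medium = NULL, id = "model") {
  S <- as.matrix(S)
  n <- length(reaction_ids)
  m <- length(metabolite_ids)
  if (ncol(S) != n) stop("S must have one column per reaction")
  if (nrow(S) != m) stop("S must have one row per metabolite")
  if (anyDuplicated(reaction_ids)) stop("duplicated reaction identifiers")
  if (anyDuplicated(metabolite_ids)) stop("duplicated metabolite identifiers")
  if (length(lower_bounds) != n || length(upper_bounds) != n)
    stop("bounds must have one entry per reaction")
  if (any(lower_bounds > upper_bounds)) {
    bad <- reaction_ids[which(lower_bounds > upper_bounds)]
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(gpr)) gpr <- rep("", n)
  if (length(gpr) != n) stop("gpr must have one entry per reaction")
  gpr[is.na(gpr)] <- ""
  for (rxn in c(biomass_reaction, target_exchange)) {
    if (!is.na(rxn) && !rxn %in% reaction_ids)
      stop("reaction '", rxn, "' is not in the model's reaction list")
  }
  ast <- lapply(gpr, parse_gpr)
  genes <- sort(unique(unlist(lapply(ast, gpr_genes))))
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  obj <- structure(list(
    id = id,
    reaction_ids = reaction_ids,
    metabolite_ids = metabolite_ids,
    S = S,
    lower_bounds = stats::setNames(as.numeric(lower_bounds), reaction_ids),
    upper_bounds = stats::setNames(as.numeric(upper_bounds), reaction_ids),
    gpr = stats::setNames(gpr, reaction_ids),
    gpr_ast = stats::setNames(ast, reaction_ids),
    genes = genes,
    biomass_reaction = biomass_reaction,
    target_exchange = target_exchange,
    medium = medium
  ), class = "metabolic_model")
  if (!is.null(medium)) obj <- apply_medium(obj, medium)
  obj
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "'\n", sep = "")
  cat("  reactions:   ", length(x$reaction_ids), "\n", sep = "")
  cat("  metabolites: ", length(x$metabolite_ids), "\n", sep = "")
  cat("  genes:       ", length(x$genes), "\n", sep = "")
  cat("  biomass:     ", x$biomass_reaction, "\n", sep = "")
  cat("  target:      ", x$target_exchange, "\n", sep = "")
  invisible(x)
}

#' Exchange reactions of a model
#'
#' An exchange (boundary) reaction has a single non-zero stoichiometric
#' coefficient; uptake is a negative flux on it (COBRA sign convention).
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction identifiers.
#' @export
exchange_reactions <- function(model) {
  nz <- colSums(model$S != 0)
  model$reaction_ids[nz == 1L]
}

#' Apply a growth medium to a model
#'
#' Sets the lower bound of each named exchange reaction to minus the given
#' uptake rate and (optionally) closes uptake through all other exchange
#' reactions, leaving secretion bounds untouched.
#'
#' @param model a `metabolic_model`.
#' @param medium named numeric vector, exchange reaction id -> maximum
#'   uptake rate (positive, mmol gDW^-1 hr^-1).
#' @param close_others close uptake (raise lower bound to 0) for exchange
#'   reactions not named in `medium`.
#' @return the modified model.
#' @export
apply_medium <- function(model, medium, close_others = TRUE) {
  unknown <- setdiff(names(medium), model$reaction_ids)
  if (length(unknown))
    stop("medium names unknown exchange reaction(s): ",
         paste(unknown, collapse = ", "))
  ex <- exchange_reactions(model)
  if (close_others) {
    shut <- setdiff(ex, names(medium))
    model$lower_bounds[shut] <- pmax(model$lower_bounds[shut], 0)
  }
  model$lower_bounds[names(medium)] <- -abs(as.numeric(medium))
  model$medium <- medium
  model
}

# ---------------------------------------------------------------------------
# GPR parsing and evaluation
#
# Grammar:  expr := term ('or' term)* ; term := factor ('and' factor)* ;
#           factor := GENE | '(' expr ')'
# 'and'/'or' are case-insensitive; gene identifiers are any other token.

parse_gpr <- function(rule) {
  rule <- trimws(rule)
  if (is.na(rule) || rule == "") return(NULL)
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    node <- parse_term()
    args <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) node else list(op = "or", args = args)
  }
  parse_term <- function() {
    node <- parse_factor()
    args <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) node else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR rule '", rule, "': unexpected end")
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")")
        stop("malformed GPR rule '", rule, "': missing ')'")
      advance()
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed GPR rule '", rule, "': unexpected '", t, "'")
    advance()
    list(op = "gene", gene = t)
  }
  node <- parse_expr()
  if (!is.na(peek()))
    stop("malformed GPR rule '", rule, "': trailing token '", peek(), "'")
  node
}

gpr_genes <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (ast$op == "gene") return(ast$gene)
  unique(unlist(lapply(ast$args, gpr_genes)))
}

# Evaluate a GPR with the genes in `knocked` absent (FALSE) and all other
# genes present (TRUE). NULL rules (no gene association) evaluate TRUE.
eval_gpr <- function(ast, knocked) {
  if (is.null(ast)) return(TRUE)
  switch(ast$op,
    gene = !(ast$gene %in% knocked),
    and  = all(vapply(ast$args, eval_gpr, logical(1), knocked = knocked)),
    or   = any(vapply(ast$args, eval_gpr, logical(1), knocked = knocked)),
    stop("corrupt GPR node")
  )
}

# ---------------------------------------------------------------------------
# Knockout sets

#' Construct a knockout set
#'
#' A knockout set couples the deleted genes with the reactions they disable
#' (the set of reactions forced to zero flux in ROOM and in the production
#' evaluator).
#'
#' @param reactions character vector of disabled reaction identifiers.
#' @param genes character vector of deleted gene identifiers (may be empty
#'   when the set was specified directly at reaction level).
#' @return an object of class `knockout_set`.
#' @export
knockout_set <- function(reactions = character(0), genes = character(0)) {
  structure(list(genes = sort(unique(genes)),
                 reactions = sort(unique(reactions))),
            class = "knockout_set")
}

#' @export
print.knockout_set <- function(x, ...) {
  cat("Knockout set: ",
      if (length(x$reactions)) paste(x$reactions, collapse = ", ")
      else "(empty)", "\n", sep = "")
  if (length(x$genes))
    cat("  from genes: ", paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reactions disabled by deleting a set of genes
#'
#' Evaluates every GPR rule with the given genes absent and all other genes
#' present; a reaction is disabled iff its rule evaluates false. Reactions
#' with no gene association are never disabled. This mapping is monotone:
#' deleting more genes can only disable more reactions.
#'
#' @param model a `metabolic_model`.
#' @param genes character vector of gene identifiers to delete.
#' @return a [knockout_set()].
#' @export
reactions_disabled_by <- function(model, genes) {
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, model$genes)
  if (length(unknown))
    stop("unknown gene identifier(s): ", paste(unknown, collapse = ", "))
  off <- vapply(model$gpr_ast, function(a) !eval_gpr(a, genes), logical(1))
  knockout_set(reactions = model$reaction_ids[off], genes = genes)
}

#' Knockout set from explicit reaction identifiers
#'
#' The reaction-level entry point used by the Bees Algorithm, which encodes
#' candidates as presence/absence vectors over the reaction list.
#'
#' @param model a `metabolic_model`.
#' @param reactions character vector of reaction identifiers to force to
#'   zero flux.
#' @return a [knockout_set()].
#' @export
knockout_reactions <- function(model, reactions) {
  reactions <- unique(as.character(reactions))
  unknown <- setdiff(reactions, model$reaction_ids)
  if (length(unknown))
    stop("unknown reaction identifier(s): ", paste(unknown, collapse = ", "))
  knockout_set(reactions = reactions)
}

# Genes whose GPR rules mention any of the given reactions; used to report
# the "associated genes" column of the knockout table.
associated_genes <- function(model, reactions) {
  sort(unique(unlist(lapply(model$gpr_ast[reactions], gpr_genes))))
}
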