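# Reading and writing standard constraint-based model formats:
# SBML Level 3 with the fbc package, and COBRA-style JSON.

#' Load a metabolic model from SBML or COBRA JSON
#'
#' Reaction order is the file's declaration order and is stable across
#' loads; bee genotypes index reactions by this order. The biomass reaction
#' defaults to the file's active flux objective; the target exchange has no
#' in-file convention and is supplied here (or set on the returned model
#' before optimization).
#'
#' @param path file path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension).
#' @param biomass,target reaction identifiers overriding / supplying the
#'   biomass reaction and target exchange.
#' @param medium optional named numeric of uptake rates, applied with
#'   [apply_medium()].
#' @return a [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "sbml", "json"),
                       biomass = NULL, target = NULL, medium = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- switch(format,
                  json = read_model_json(path),
                  sbml = read_model_sbml(path))
  if (!is.null(biomass)) {
    if (!biomass %in% model$reaction_ids)
      stop("biomass reaction '", biomass, "' not in model")
    model$biomass_reaction <- biomass
  }
  if (!is.null(target)) {
    if (!target %in% model$reaction_ids)
      stop("target exchange '", target, "' not in model")
    model$target_exchange <- target
  }
  if (!is.null(medium)) model <- apply_medium(model, medium)
  model
}

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$reactions) || is.null(doc$metabolites))
    stop("not a COBRA JSON model: missing 'reactions' or 'metabolites'")
  met_ids <- vapply(doc$metabolites, function(m) m$id, character(1))
  rxn_ids <- vapply(doc$reactions, function(r) r$id, character(1))
  n <- length(rxn_ids); m <- length(met_ids)
  S <- matrix(0, m, n)
  lb <- numeric(n); ub <- numeric(n); gpr <- character(n)
  obj_coef <- numeric(n)
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    if (is.null(r$lower_bound) || is.null(r$upper_bound))
      stop("reaction '", r$id, "' has no flux bounds")
    lb[j] <- as.numeric(r$lower_bound)
    ub[j] <- as.numeric(r$upper_bound)
    gpr[j] <- if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule
    obj_coef[j] <- if (is.null(r$objective_coefficient)) 0
                   else as.numeric(r$objective_coefficient)
    for (met in names(r$metabolites)) {
      i <- match(met, met_ids)
      if (is.na(i)) stop("reaction '", r$id, "' references unknown metabolite '",
                         met, "'")
      S[i, j] <- as.numeric(r$metabolites[[met]])
    }
  }
  biomass <- NA_character_
  if (any(obj_coef != 0)) biomass <- rxn_ids[which(obj_coef != 0)[1]]
  extra <- list(biomass = doc$beeknock_biomass, target = doc$beeknock_target)
  if (!is.null(extra$biomass)) biomass <- extra$biomass
  target <- if (!is.null(extra$target)) extra$target else NA_character_
  metabolic_model(rxn_ids, met_ids, S, lb, ub, gpr,
                  biomass_reaction = biomass, target_exchange = target,
                  id = if (!is.null(doc$id)) doc$id else "model")
}

#' Write a model as COBRA-style JSON
#'
#' Inverse of the JSON reader: `load_model(write_model_json(model, path))`
#' reproduces the stoichiometry, bounds, GPR strings and reaction order
#' exactly.
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    col <- model$S[, j]
    nz <- which(col != 0)
    r <- list(
      id = model$reaction_ids[j],
      metabolites = as.list(stats::setNames(col[nz], model$metabolite_ids[nz])),
      lower_bound = unname(model$lower_bounds[j]),
      upper_bound = unname(model$upper_bounds[j]),
      gene_reaction_rule = unname(model$gpr[j])
    )
    if (!is.na(model$biomass_reaction) &&
        model$reaction_ids[j] == model$biomass_reaction)
      r$objective_coefficient <- 1
    r
  })
  doc <- list(
    id = model$id,
    metabolites = lapply(model$metabolite_ids, function(m) list(id = m)),
    reactions = rxns,
    genes = lapply(model$genes, function(g) list(id = g))
  )
  if (!is.na(model$target_exchange)) doc$beeknock_target <- model$target_exchange
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SBML Level 3 + fbc

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model_node, "xml_missing")) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  sp_ids <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  met_ids <- sp_ids[!sp_boundary]

  gps <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_label <- stats::setNames(xml2::xml_attr(gps, "label"),
                              xml2::xml_attr(gps, "id"))
  gp_label[is.na(gp_label)] <- names(gp_label)[is.na(gp_label)]

  rxn_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (!length(rxn_nodes)) stop("no reactions in ", path)
  n <- length(rxn_nodes); m <- length(met_ids)
  rxn_ids <- xml2::xml_attr(rxn_nodes, "id")
  S <- matrix(0, m, n)
  lb <- numeric(n); ub <- numeric(n); gpr <- character(n)
  for (j in seq_len(n)) {
    node <- rxn_nodes[[j]]
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref))
      stop("reaction '", rxn_ids[j], "' has no fbc flux bounds")
    if (!lb_ref %in% names(pval) || !ub_ref %in% names(pval))
      stop("reaction '", rxn_ids[j], "' references undefined bound parameter")
    lb[j] <- pval[[lb_ref]]
    ub[j] <- pval[[ub_ref]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(
        node, paste0("./*[local-name()='", side,
                     "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        i <- match(sp, met_ids)
        if (!is.na(i)) S[i, j] <- S[i, j] + sgn * st
        # boundary species are omitted from mass balance
      }
    }
    gpa <- xml2::xml_find_first(
      node, "./*[local-name()='geneProductAssociation']")
    gpr[j] <- if (inherits(gpa, "xml_missing")) "" else
      sbml_gpa_string(xml2::xml_children(gpa)[[1]], gp_label)
  }

  biomass <- NA_character_
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    biomass <- xml2::xml_attr(fo, "reaction")
    if (!biomass %in% rxn_ids) biomass <- NA_character_
  }
  metabolic_model(rxn_ids, met_ids, S, lb, ub, gpr,
                  biomass_reaction = biomass, id = model_id)
}

# Render an fbc geneProductAssociation subtree as an "a and (b or c)" string.
sbml_gpa_string <- function(node, gp_label) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    id <- xml2::xml_attr(node, "geneProduct")
    lab <- gp_label[[id]]
    return(if (is.null(lab) || is.na(lab)) id else lab)
  }
  if (name %in% c("and", "or")) {
    parts <- vapply(xml2::xml_children(node), sbml_gpa_string, character(1),
                    gp_label = gp_label)
    wrapped <- vapply(parts, function(p) {
      if (grepl(" ", p)) paste0("(", p, ")") else p
    }, character(1))
    return(paste(wrapped, collapse = paste0(" ", name, " ")))
  }
  stop("unsupported element '", name, "' in geneProductAssociation")
}

#' Write a model as SBML Level 3 with fbc
#'
#' Emits a minimal fbc-compliant document (bounds as global parameters, GPR
#' rules as geneProductAssociations, biomass as the active flux objective)
#' that round-trips through the SBML reader and loads in standard COBRA
#' toolboxes.
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  gpa_xml <- function(ast) {
    if (ast$op == "gene")
      return(sprintf("<fbc:geneProductRef fbc:geneProduct=\"G_%s\"/>",
                     esc(ast$gene)))
    inner <- paste(vapply(ast$args, gpa_xml, character(1)), collapse = "")
    sprintf("<fbc:%s>%s</fbc:%s>", ast$op, inner, ast$op)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("<model id=\"%s\" fbc:strict=\"true\">", esc(model$id)),
    "<listOfCompartments><compartment id=\"c\" constant=\"true\"/></listOfCompartments>",
    "<listOfSpecies>",
    sprintf(paste0("<species id=\"%s\" compartment=\"c\" ",
                   "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
                   "constant=\"false\"/>"), esc(model$metabolite_ids)),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf("<parameter id=\"bk_lb_%d\" value=\"%s\" constant=\"true\"/>",
            seq_along(model$reaction_ids), num(model$lower_bounds)),
    sprintf("<parameter id=\"bk_ub_%d\" value=\"%s\" constant=\"true\"/>",
            seq_along(model$reaction_ids), num(model$upper_bounds)),
    "</listOfParameters>"
  )
  if (length(model$genes)) {
    lines <- c(lines, "<fbc:listOfGeneProducts>",
               sprintf("<fbc:geneProduct fbc:id=\"G_%s\" fbc:label=\"%s\"/>",
                       esc(model$genes), esc(model$genes)),
               "</fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "<listOfReactions>")
  for (j in seq_along(model$reaction_ids)) {
    col <- model$S[, j]
    reac <- which(col < 0); prod <- which(col > 0)
    side <- function(idx, tag) {
      if (!length(idx)) return(character(0))
      c(sprintf("<%s>", tag),
        sprintf(paste0("<speciesReference species=\"%s\" ",
                       "stoichiometry=\"%s\" constant=\"true\"/>"),
                esc(model$metabolite_ids[idx]), num(abs(col[idx]))),
        sprintf("</%s>", tag))
    }
    gpa <- if (!is.null(model$gpr_ast[[j]])) {
      c("<fbc:geneProductAssociation>",
        gpa_xml(model$gpr_ast[[j]]),
        "</fbc:geneProductAssociation>")
    } else character(0)
    lines <- c(lines,
      sprintf(paste0("<reaction id=\"%s\" reversible=\"%s\" fast=\"false\" ",
                     "fbc:lowerFluxBound=\"bk_lb_%d\" ",
                     "fbc:upperFluxBound=\"bk_ub_%d\">"),
              esc(model$reaction_ids[j]),
              if (model$lower_bounds[j] < 0) "true" else "false", j, j),
      side(reac, "listOfReactants"),
      side(prod, "listOfProducts"),
      gpa,
      "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>")
  if (!is.na(model$biomass_reaction)) {
    lines <- c(lines,
      "<fbc:listOfObjectives fbc:activeObjective=\"obj\">",
      "<fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
      "<fbc:listOfFluxObjectives>",
      sprintf(paste0("<fbc:fluxObjective fbc:reaction=\"%s\" ",
                     "fbc:coefficient=\"1\"/>"), esc(model$biomass_reaction)),
      "</fbc:listOfFluxObjectives>",
      "</fbc:objective>",
      "</fbc:listOfObjectives>")
  }
  lines <- c(lines, "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
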