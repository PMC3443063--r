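#' Read a metabolic model from SBML
#'
#' Reads SBML Level 2 Version 4 in the COBRA dialect (GPRs as
#' `GENE_ASSOCIATION:` lines in reaction notes, bounds as `LOWER_BOUND` /
#' `UPPER_BOUND` kinetic-law parameters, objective as
#' `OBJECTIVE_COEFFICIENT`), and additionally SBML files carrying fbc-v2
#' gene-product associations, flux bounds and objectives.
#'
#' The reader is strict on XML structure but lenient on GPR text: a reaction
#' whose gene-association string cannot be parsed is kept with no association
#' and a warning; diagnostics are attached to the returned model as the
#' `gpr_diagnostics` attribute. Bounds default to (-1000, 1000) for reactions
#' marked reversible and (0, 1000) otherwise.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_model].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("SBML parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  has_fbc <- any(grepl("fbc", names(xml2::xml_ns(doc)), fixed = TRUE)) ||
    any(grepl("/fbc/", unlist(xml2::xml_ns(doc)), fixed = TRUE))
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, "./model")
  if (inherits(model_node, "xml_missing")) stop("no <model> element in ", path)
  model_id <- attr_or(model_node, "id", "model")

  comp_nodes <- xml2::xml_find_all(model_node, "./listOfCompartments/compartment")
  compartments <- data.frame(
    id = vapply(comp_nodes, attr_or, character(1), "id", ""),
    name = vapply(comp_nodes, attr_or, character(1), "name", ""),
    stringsAsFactors = FALSE
  )

  sp_nodes <- xml2::xml_find_all(model_node, "./listOfSpecies/species")
  metabolites <- data.frame(
    id = vapply(sp_nodes, attr_or, character(1), "id", ""),
    name = vapply(sp_nodes, attr_or, character(1), "name", ""),
    compartment = vapply(sp_nodes, attr_or, character(1), "compartment", ""),
    boundary = vapply(sp_nodes, attr_or, character(1), "boundaryCondition", "false") == "true",
    stringsAsFactors = FALSE
  )

  # global parameters (fbc flux bounds refer to these)
  par_nodes <- xml2::xml_find_all(model_node, "./listOfParameters/parameter")
  global_par <- stats::setNames(
    as.numeric(vapply(par_nodes, attr_or, character(1), "value", "NA")),
    vapply(par_nodes, attr_or, character(1), "id", "")
  )

  # fbc gene products: internal id -> label (the gene identifier)
  gp_nodes <- xml2::xml_find_all(model_node, ".//*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    vapply(gp_nodes, fbc_attr, character(1), "label"),
    vapply(gp_nodes, fbc_attr, character(1), "id")
  )
  fbc_objective <- NA_character_
  fo <- xml2::xml_find_first(model_node, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) fbc_objective <- fbc_attr(fo, "reaction")

  rxn_nodes <- xml2::xml_find_all(model_node, "./listOfReactions/reaction")
  n <- length(rxn_nodes)
  ids <- character(n); nms <- character(n); lbs <- numeric(n); ubs <- numeric(n)
  ecs <- rep(NA_character_, n)
  stoich <- vector("list", n)
  gprs <- vector("list", n)
  diagnostics <- list()
  biomass <- NA_character_

  for (k in seq_len(n)) {
    rn <- rxn_nodes[[k]]
    rid <- attr_or(rn, "id", paste0("rxn_", k))
    ids[k] <- rid
    nms[k] <- attr_or(rn, "name", "")
    reversible <- attr_or(rn, "reversible", "true") == "true"

    st <- c(read_species_refs(rn, "listOfReactants", -1),
            read_species_refs(rn, "listOfProducts", +1))
    st <- tapply(st, names(st), sum)  # merge duplicated species refs
    stoich[[k]] <- stats::setNames(as.numeric(st), names(st))

    # bounds: COBRA kinetic-law parameters, else fbc, else reversibility default
    lb <- if (reversible) -1000 else 0
    ub <- 1000
    kl <- xml2::xml_find_all(rn, "./kineticLaw/listOfParameters/parameter")
    obj_coef <- 0
    if (length(kl)) {
      pid <- vapply(kl, attr_or, character(1), "id", "")
      pval <- as.numeric(vapply(kl, attr_or, character(1), "value", "NA"))
      if ("LOWER_BOUND" %in% pid) lb <- pval[match("LOWER_BOUND", pid)]
      if ("UPPER_BOUND" %in% pid) ub <- pval[match("UPPER_BOUND", pid)]
      if ("OBJECTIVE_COEFFICIENT" %in% pid) obj_coef <- pval[match("OBJECTIVE_COEFFICIENT", pid)]
    }
    lb_ref <- fbc_attr(rn, "lowerFluxBound")
    ub_ref <- fbc_attr(rn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(global_par)) lb <- global_par[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(global_par)) ub <- global_par[[ub_ref]]
    lbs[k] <- lb; ubs[k] <- ub
    if (!is.na(obj_coef) && obj_coef != 0 && is.na(biomass)) biomass <- rid

    # GPR: fbc geneProductAssociation preferred, else COBRA notes line
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    if (has_fbc && !inherits(gpa, "xml_missing")) {
      kid <- xml2::xml_find_first(gpa, "./*")
      tree <- fbc_gpr_tree(kid, gp_label)
      if (!is.null(tree)) gprs[k] <- list(tree)
    } else {
      lines <- notes_lines(rn)
      ga <- grep("^\\s*GENE[ _]?ASSOCIATION\\s*:", lines, value = TRUE)
      if (length(ga)) {
        txt <- trimws(sub("^\\s*GENE[ _]?ASSOCIATION\\s*:", "", ga[[1L]]))
        g <- tryCatch(parse_gpr(txt), error = function(e) {
          warning("reaction ", rid, ": unparseable GENE_ASSOCIATION kept as absent (",
                  conditionMessage(e), ")", call. = FALSE)
          diagnostics[[length(diagnostics) + 1L]] <<-
            data.frame(reaction = rid, text = txt, message = conditionMessage(e),
                       stringsAsFactors = FALSE)
          NULL
        })
        if (!is.null(g)) gprs[k] <- list(g)
      }
      ec <- grep("^\\s*EC[ _]?NUMBER\\s*:", lines, value = TRUE)
      if (length(ec)) ecs[k] <- trimws(sub("^\\s*EC[ _]?NUMBER\\s*:", "", ec[[1L]]))
    }
  }

  names(stoich) <- ids
  names(gprs) <- ids
  gprs <- gprs[!vapply(gprs, is.null, logical(1))]
  if (!is.na(fbc_objective)) biomass <- fbc_objective

  categories <- vapply(seq_len(n), function(k) {
    classify_reaction_category(stoich[[k]], metabolites)
  }, character(1))

  m <- metabolic_model(
    id = model_id,
    compartments = compartments,
    metabolites = metabolites,
    reactions = data.frame(id = ids, name = nms, lower_bound = lbs,
                           upper_bound = ubs, category = categories, ec = ecs,
                           stringsAsFactors = FALSE),
    stoichiometry = stoich,
    gpr = gprs,
    biomass_reaction = biomass
  )
  if (length(diagnostics)) {
    attr(m, "gpr_diagnostics") <- do.call(rbind, diagnostics)
  }
  m
}

attr_or <- function(node, name, default = NA_character_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

# fbc attributes keep their prefix after xml_ns_strip(); try both spellings
fbc_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) %in% c(name, paste0("fbc:", name)))
  if (length(hit)) at[[hit[[1L]]]] else NA_character_
}

read_species_refs <- function(rxn_node, list_name, sign) {
  refs <- xml2::xml_find_all(rxn_node, paste0("./", list_name, "/speciesReference"))
  if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
  sp <- vapply(refs, attr_or, character(1), "species", "")
  coef <- as.numeric(vapply(refs, attr_or, character(1), "stoichiometry", "1"))
  stats::setNames(sign * coef, sp)
}

# text lines inside a reaction's <notes>, one per leaf element
notes_lines <- function(rxn_node) {
  notes <- xml2::xml_find_first(rxn_node, "./notes")
  if (inherits(notes, "xml_missing")) return(character(0))
  leaves <- xml2::xml_find_all(notes, ".//*[not(*)]")
  if (!length(leaves)) return(xml2::xml_text(notes))
  vapply(leaves, xml2::xml_text, character(1))
}

fbc_gpr_tree <- function(node, gp_label) {
  if (inherits(node, "xml_missing") || is.null(node)) return(NULL)
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- fbc_attr(node, "geneProduct")
    lab <- if (ref %in% names(gp_label) && nzchar(gp_label[[ref]])) gp_label[[ref]] else ref
    return(gpr_leaf(lab))
  }
  kids <- lapply(xml2::xml_find_all(node, "./*"), fbc_gpr_tree, gp_label = gp_label)
  new_gpr_node(if (nm == "and") "and" else "or", kids)
}

#' Write a metabolic model as SBML Level 2 Version 4
#'
#' Emits the COBRA dialect: GPRs as `GENE_ASSOCIATION:` notes lines
#' (reactions without a gene association get no such line), EC numbers as
#' `EC_NUMBER:` lines, flux bounds as `LOWER_BOUND`/`UPPER_BOUND` kinetic-law
#' parameters and the biomass objective as `OBJECTIVE_COEFFICIENT 1`.
#' [read_sbml()] applied to the written file returns a model isomorphic to
#' the input.
#'
#' @param m A [metabolic_model].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(m, path) {
  validate_metabolic_model(m)
  num <- function(x) sprintf("%.17g", x)
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level2/version4",
    level = "2", version = "4")
  mod <- xml2::xml_add_child(doc, "model", id = m$id)

  loc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (i in seq_len(nrow(m$compartments))) {
    xml2::xml_add_child(loc, "compartment",
                        id = m$compartments$id[i], name = m$compartments$name[i])
  }
  los <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(m$metabolites))) {
    xml2::xml_add_child(los, "species",
      id = m$metabolites$id[i], name = m$metabolites$name[i],
      compartment = m$metabolites$compartment[i],
      boundaryCondition = if (m$metabolites$boundary[i]) "true" else "false")
  }
  lor <- xml2::xml_add_child(mod, "listOfReactions")
  for (i in seq_len(nrow(m$reactions))) {
    rid <- m$reactions$id[i]
    lb <- m$reactions$lower_bound[i]
    ub <- m$reactions$upper_bound[i]
    rn <- xml2::xml_add_child(lor, "reaction",
      id = rid, name = m$reactions$name[i],
      reversible = if (lb < 0) "true" else "false")
    ga <- m$gpr[[rid]]
    ec <- m$reactions$ec[i]
    if (!is.null(ga) || !is.na(ec)) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      if (!is.null(ga)) {
        p <- xml2::xml_add_child(body, "p")
        xml2::xml_set_text(p, paste0("GENE_ASSOCIATION: ", gpr_to_string(ga)))
      }
      if (!is.na(ec)) {
        p <- xml2::xml_add_child(body, "p")
        xml2::xml_set_text(p, paste0("EC_NUMBER: ", ec))
      }
    }
    st <- m$stoichiometry[[rid]]
    subs <- st[st < 0]
    prods <- st[st > 0]
    if (length(subs)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (sp in names(subs)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = sp, stoichiometry = num(-subs[[sp]]))
      }
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (sp in names(prods)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = sp, stoichiometry = num(prods[[sp]]))
      }
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    ci <- xml2::xml_add_child(math, "ci")
    xml2::xml_set_text(ci, " FLUX_VALUE ")
    lop <- xml2::xml_add_child(kl, "listOfParameters")
    xml2::xml_add_child(lop, "parameter", id = "LOWER_BOUND", value = num(lb),
                        units = "mmol_per_gDW_per_hr")
    xml2::xml_add_child(lop, "parameter", id = "UPPER_BOUND", value = num(ub),
                        units = "mmol_per_gDW_per_hr")
    xml2::xml_add_child(lop, "parameter", id = "OBJECTIVE_COEFFICIENT",
      value = if (!is.na(m$biomass_reaction) && rid == m$biomass_reaction) "1" else "0")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
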