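#' Options controlling model projection
#'
#' @param keep_spontaneous Copy reactions without a gene association
#'   (spontaneous enzymatic and non-enzymatic transport reactions) verbatim.
#'   Default `TRUE`, as projection keeps all relevant non-enzymatic
#'   transports and compartments.
#' @param keep_exchanges Copy exchange reactions verbatim. Default `TRUE`.
#' @param conservation_rule `"any-complete-gene-set"` (default): a
#'   GPR-bearing reaction is conserved iff its rewritten association retains
#'   at least one complete minimal gene set. `"any-mapped-leaf"`: conserved
#'   as soon as any scaffold gene of the formula has a mapping; if the
#'   rewritten formula is unsatisfiable the mapped targets are joined by OR.
#' @param biomass A [biomass_adjustment()], or `NULL` to keep the scaffold's
#'   biomass coefficients.
#' @param curation Optional curation override `data.frame` with columns
#'   `reaction_id`, `verdict` (`"Lost"` or `"Retained"`) and optionally
#'   `note`: `Retained` force-copies a reaction without gene association,
#'   `Lost` force-drops it.
#' @return An object of class `projection_options`.
#' @export
projection_options <- function(keep_spontaneous = TRUE, keep_exchanges = TRUE,
                               conservation_rule = c("any-complete-gene-set",
                                                     "any-mapped-leaf"),
                               biomass = NULL, curation = NULL) {
  conservation_rule <- match.arg(conservation_rule)
  if (!is.null(curation)) {
    stopifnot(all(c("reaction_id", "verdict") %in% names(curation)),
              all(curation$verdict %in% c("Lost", "Retained")))
  }
  structure(list(keep_spontaneous = keep_spontaneous,
                 keep_exchanges = keep_exchanges,
                 conservation_rule = conservation_rule,
                 biomass = biomass, curation = curation),
            class = "projection_options")
}

#' Biomass DNA-precursor adjustment
#'
#' Describes how to re-balance the biomass function's deoxynucleotide
#' precursors for the target genome: dGTP and dCTP each receive a share
#' proportional to `gc_content / 2`, dATP and dTTP to `(1 - gc_content) / 2`,
#' scaled so the summed precursor coefficient equals `dna_mass_fraction`
#' (or the scaffold's original sum when `NULL`).
#'
#' @param gc_content GC fraction of the target genome, in (0, 1).
#' @param genome_length Target genome length in base pairs (> 0); recorded
#'   for provenance and available for computing `dna_mass_fraction` upstream.
#' @param dna_mass_fraction Total DNA precursor demand, same units as the
#'   biomass coefficients (mmol/gDW); `NULL` keeps the scaffold's total.
#' @return An object of class `biomass_adjustment`.
#' @export
biomass_adjustment <- function(gc_content, genome_length,
                               dna_mass_fraction = NULL) {
  stopifnot(is.numeric(gc_content), gc_content > 0, gc_content < 1,
            is.numeric(genome_length), genome_length > 0)
  structure(list(gc_content = gc_content, genome_length = genome_length,
                 dna_mass_fraction = dna_mass_fraction),
            class = "biomass_adjustment")
}

#' Project a scaffold model onto a target species
#'
#' For every scaffold reaction with a gene association, the GPR is rewritten
#' through the consensus homolog map ([rewrite_gpr()]); the reaction is
#' conserved (copied with the new association) when the conservation rule is
#' met, otherwise reported as lost for manual review. Reactions without gene
#' association — spontaneous reactions, non-enzymatic transports and
#' exchanges — are copied verbatim under the corresponding options, as are
#' all compartments. Metabolites are restricted to those referenced by the
#' surviving reactions (plus the biomass precursors). Metabolite identifiers
#' and annotations are preserved from the scaffold.
#'
#' @param scaffold A [metabolic_model] with a biomass reaction.
#' @param map A [build_consensus()] result or named list (see
#'   [rewrite_gpr()]).
#' @param opts A [projection_options()].
#' @param target_id Id for the projected model.
#' @return A list with `model` (the projected [metabolic_model]) and
#'   `report` (class `projection_report`): `conserved` (`data.frame` of
#'   reaction id, case label, unresolved genes), `rewrites` (named list of
#'   [rewrite_gpr()] results), `lost`, `dropped`, `gained` (reaction ids)
#'   and `unresolved_genes`.
#' @export
project <- function(scaffold, map, opts = projection_options(),
                    target_id = paste0(scaffold$id, "_projected")) {
  validate_metabolic_model(scaffold)
  if (is.na(scaffold$biomass_reaction)) {
    stop("scaffold has no biomass reaction; cannot produce a functional model")
  }
  cur <- opts$curation
  verdict_of <- function(rid) {
    if (is.null(cur)) return(NA_character_)
    i <- match(rid, cur$reaction_id)
    if (is.na(i)) NA_character_ else cur$verdict[i]
  }

  keep <- character(0)
  new_gpr <- list()
  conserved <- data.frame(reaction = character(0), case = character(0),
                          unresolved = character(0), stringsAsFactors = FALSE)
  rewrites <- list()
  lost <- character(0)
  dropped <- character(0)
  unresolved_all <- character(0)

  for (rid in scaffold$reactions$id) {
    ga <- scaffold$gpr[[rid]]
    v <- verdict_of(rid)
    if (identical(v, "Lost")) {
      lost <- c(lost, rid)
      next
    }
    if (identical(v, "Retained")) {
      keep <- c(keep, rid)
      conserved[nrow(conserved) + 1L, ] <- list(rid, "retained", "")
      next
    }
    if (is.null(ga)) {
      category <- scaffold$reactions$category[match(rid, scaffold$reactions$id)]
      ok <- if (category == "exchange") opts$keep_exchanges else opts$keep_spontaneous
      if (rid == scaffold$biomass_reaction) ok <- TRUE
      if (ok) keep <- c(keep, rid) else dropped <- c(dropped, rid)
      next
    }
    rw <- rewrite_gpr(ga, map)
    rewrites[[rid]] <- rw
    unresolved_all <- union(unresolved_all, rw$unresolved_genes)
    is_conserved <- if (opts$conservation_rule == "any-complete-gene-set") {
      !is.null(rw$new_association)
    } else {
      length(rw$unresolved_genes) < length(gpr_genes(ga))
    }
    if (!is_conserved) {
      lost <- c(lost, rid)
      next
    }
    ga_new <- rw$new_association
    if (is.null(ga_new)) {
      # any-mapped-leaf rule with a broken formula: join mapped targets by OR
      lookup <- homolog_lookup(map)
      tg <- sort(unique(unlist(lapply(gpr_genes(ga), lookup))))
      ga_new <- new_gpr_node("or", lapply(tg, gpr_leaf))
    }
    keep <- c(keep, rid)
    new_gpr[[rid]] <- ga_new
    conserved[nrow(conserved) + 1L, ] <-
      list(rid, rw$case_label, paste(rw$unresolved_genes, collapse = ";"))
  }

  ridx <- match(keep, scaffold$reactions$id)
  reactions <- scaffold$reactions[ridx, , drop = FALSE]
  rownames(reactions) <- NULL
  stoich <- scaffold$stoichiometry[keep]
  used_mets <- unique(c(unlist(lapply(stoich, names)),
                        names(scaffold$stoichiometry[[scaffold$biomass_reaction]])))
  metabolites <- scaffold$metabolites[scaffold$metabolites$id %in% used_mets, ,
                                      drop = FALSE]
  rownames(metabolites) <- NULL

  model <- metabolic_model(
    id = target_id,
    compartments = scaffold$compartments,
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoich,
    gpr = new_gpr,
    biomass_reaction = scaffold$biomass_reaction
  )
  if (!is.null(opts$biomass)) model <- adjust_biomass(model, opts$biomass)

  report <- structure(
    list(conserved = conserved, rewrites = rewrites, lost = lost,
         dropped = dropped, gained = character(0),
         unresolved_genes = sort(unresolved_all)),
    class = "projection_report"
  )
  list(model = model, report = report)
}

#' @export
print.projection_report <- function(x, ...) {
  cat("<projection_report>\n",
      "  conserved: ", nrow(x$conserved), "\n",
      "  lost:      ", length(x$lost), "\n",
      "  dropped:   ", length(x$dropped), "\n",
      "  gained:    ", length(x$gained), "\n",
      "  unresolved genes: ", length(x$unresolved_genes), "\n", sep = "")
  if (nrow(x$conserved)) {
    print(table(x$conserved$case))
  }
  invisible(x)
}

#' Insert species-specific reactions
#'
#' Adds target-only reactions (gene gains, case M2) to a projected model:
#' reactions supported by target genes with no scaffold counterpart, e.g.
#' enzymes found by EC annotation, or new transports. Referenced metabolites
#' that do not exist yet are created in their declared compartments.
#'
#' @param model A [metabolic_model].
#' @param reactions A list; each element a list with fields `id`, `name`,
#'   `stoichiometry` (named numeric), optional `lower_bound`, `upper_bound`,
#'   `gpr` (string or [gpr] tree), `category`, `ec`, and
#'   `metabolite_compartments` (named character: compartment for each new
#'   metabolite; defaults to the model's first compartment).
#' @param report Optional [project()] report whose `gained` list is extended.
#' @return The extended model; when `report` is given, a list
#'   `list(model, report)`.
#' @export
add_species_specific <- function(model, reactions, report = NULL) {
  validate_metabolic_model(model)
  for (r in reactions) {
    if (r$id %in% model$reactions$id) {
      stop("reaction id collision: ", r$id)
    }
    st <- r$stoichiometry
    new_mets <- setdiff(names(st), model$metabolites$id)
    mc <- r$metabolite_compartments
    for (nm in new_mets) {
      comp <- if (!is.null(mc) && nm %in% names(mc)) mc[[nm]] else model$compartments$id[1L]
      model$metabolites[nrow(model$metabolites) + 1L, ] <-
        list(id = nm, name = nm, compartment = comp, boundary = FALSE)
    }
    ga <- r$gpr
    if (is.character(ga)) ga <- parse_gpr(ga)
    lb <- if (is.null(r$lower_bound)) 0 else r$lower_bound
    ub <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
    category <- if (is.null(r$category)) {
      classify_reaction_category(st, model$metabolites)
    } else r$category
    model$reactions[nrow(model$reactions) + 1L, ] <-
      list(id = r$id, name = if (is.null(r$name)) r$id else r$name,
           lower_bound = lb, upper_bound = ub, category = category,
           ec = if (is.null(r$ec)) NA_character_ else r$ec)
    model$stoichiometry[[r$id]] <- st
    if (!is.null(ga)) {
      model$gpr[[r$id]] <- ga
      model$genes <- sort(union(model$genes, gpr_genes(ga)))
    }
    if (!is.null(report)) report$gained <- c(report$gained, r$id)
  }
  validate_metabolic_model(model)
  if (is.null(report)) model else list(model = model, report = report)
}

#' Re-balance the biomass DNA precursors
#'
#' Applies a [biomass_adjustment()]: the four deoxynucleotide precursor
#' coefficients of the biomass reaction are replaced by GC-proportional
#' shares (dGTP, dCTP proportional to `gc/2`; dATP, dTTP to `(1-gc)/2`),
#' scaled so their sum equals `dna_mass_fraction`, or the scaffold's original
#' summed coefficient when that is `NULL`. All other biomass coefficients
#' are unchanged.
#'
#' @param model A [metabolic_model] whose biomass reaction consumes the four
#'   precursors.
#' @param adj A [biomass_adjustment()].
#' @param precursor_ids Named character vector mapping roles `dATP`, `dCTP`,
#'   `dGTP`, `dTTP` to metabolite ids in the model.
#' @return The adjusted model.
#' @export
adjust_biomass <- function(model, adj,
                           precursor_ids = c(dATP = "dATP_c", dCTP = "dCTP_c",
                                             dGTP = "dGTP_c", dTTP = "dTTP_c")) {
  stopifnot(inherits(adj, "biomass_adjustment"),
            setequal(names(precursor_ids), c("dATP", "dCTP", "dGTP", "dTTP")))
  if (is.na(model$biomass_reaction)) stop("model has no biomass reaction")
  st <- model$stoichiometry[[model$biomass_reaction]]
  missing <- setdiff(unname(precursor_ids), names(st))
  if (length(missing)) {
    stop("biomass reaction lacks DNA precursor(s): ",
         paste(missing, collapse = ", "))
  }
  total <- if (is.null(adj$dna_mass_fraction)) {
    sum(abs(st[unname(precursor_ids)]))
  } else {
    adj$dna_mass_fraction
  }
  gc <- adj$gc_content
  share <- c(dATP = (1 - gc) / 2, dCTP = gc / 2, dGTP = gc / 2,
             dTTP = (1 - gc) / 2)
  st[unname(precursor_ids)] <- -total * share[names(precursor_ids)]
  model$stoichiometry[[model$biomass_reaction]] <- st
  model
}

#' Read a curation override table
#'
#' TSV with columns `reaction_id`, `verdict` (`Lost`/`Retained`) and an
#' optional `note`, mirroring a manual review of lost-reaction predictions.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` usable as `curation` in [projection_options()].
#' @export
read_curation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "verdict") %in% names(df)))
  if (!all(df$verdict %in% c("Lost", "Retained"))) {
    stop("curation verdicts must be 'Lost' or 'Retained'")
  }
  df
}

#' Write a projection report as TSV and JSON
#'
#' @param report A [project()] report.
#' @param tsv,json Output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_projection_report <- function(report, tsv = NULL, json = NULL) {
  df <- rbind(
    data.frame(reaction = report$conserved$reaction, status = "conserved",
               case = report$conserved$case,
               unresolved = report$conserved$unresolved,
               stringsAsFactors = FALSE),
    data.frame(reaction = report$lost, status = "lost", case = "M1",
               unresolved = "", stringsAsFactors = FALSE),
    data.frame(reaction = report$dropped, status = "dropped", case = "",
               unresolved = "", stringsAsFactors = FALSE),
    data.frame(reaction = report$gained, status = "gained", case = "M2",
               unresolved = "", stringsAsFactors = FALSE)
  )
  if (!is.null(tsv)) {
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(conserved = report$conserved, lost = report$lost,
           dropped = report$dropped, gained = report$gained,
           unresolved_genes = report$unresolved_genes),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
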