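#' Detect network gaps
#'
#' Finds structural dead-end metabolites (producible but never consumable, or
#' vice versa, accounting for reaction reversibility; boundary species are
#' excluded), reactions blocked under the given media (flux-variability range
#' identically zero within 1e-9), and biomass precursors that cannot be
#' produced from the media (maximal flux of a temporary sink is zero).
#'
#' @param model A [metabolic_model].
#' @param media Optional [media_condition] (or preset name) applied before
#'   the flux computations; `NULL` analyses the model's current bounds.
#' @param config Optional [media_config] for `media`.
#' @return An object of class `gap_report`: list with `dead_end_metabolites`
#'   (`data.frame`: `metabolite`, `role` in `never-produced` /
#'   `never-consumed`), `blocked_reactions`, `disconnected_biomass_precursors`
#'   and `diagnostic` (`NA`, or a note when the LP under the media was
#'   infeasible and all reactions are reported blocked).
#' @export
find_gaps <- function(model, media = NULL, config = NULL) {
  validate_metabolic_model(model)
  if (!is.null(media)) model <- apply_media(model, media, config)

  # structural dead ends
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  dead <- data.frame(metabolite = character(0), role = character(0),
                     stringsAsFactors = FALSE)
  nonb <- model$metabolites$id[!model$metabolites$boundary]
  for (met in nonb) {
    producible <- FALSE
    consumable <- FALSE
    for (j in seq_along(model$stoichiometry)) {
      coef <- model$stoichiometry[[j]][met]
      if (is.na(coef)) next
      if ((coef > 0 && ub[j] > 0) || (coef < 0 && lb[j] < 0)) producible <- TRUE
      if ((coef < 0 && ub[j] > 0) || (coef > 0 && lb[j] < 0)) consumable <- TRUE
      if (producible && consumable) break
    }
    if (producible && !consumable) {
      dead[nrow(dead) + 1L, ] <- list(met, "never-consumed")
    } else if (consumable && !producible) {
      dead[nrow(dead) + 1L, ] <- list(met, "never-produced")
    }
  }

  diagnostic <- NA_character_
  base <- fba(model)
  if (base$status != "optimal") {
    blocked <- model$reactions$id
    diagnostic <- "LP infeasible under the given media; all reactions reported blocked"
  } else {
    fv <- flux_variability(model)
    blocked <- fv$reaction[!is.na(fv$min) & !is.na(fv$max) &
                             abs(fv$min) < 1e-9 & abs(fv$max) < 1e-9]
  }

  disconnected <- character(0)
  if (!is.na(model$biomass_reaction)) {
    st <- model$stoichiometry[[model$biomass_reaction]]
    precursors <- names(st)[st < 0]
    for (met in precursors) {
      if (max_production(model, met) < 1e-9) disconnected <- c(disconnected, met)
    }
  }

  structure(list(dead_end_metabolites = dead, blocked_reactions = blocked,
                 disconnected_biomass_precursors = disconnected,
                 diagnostic = diagnostic),
            class = "gap_report")
}

# maximal flux through a temporary sink of `met` (0 when infeasible)
max_production <- function(model, met) {
  sink_id <- ".tmp_sink"
  model$reactions[nrow(model$reactions) + 1L, ] <-
    list(id = sink_id, name = "", lower_bound = 0, upper_bound = 1000,
         category = "exchange", ec = NA_character_)
  model$stoichiometry[[sink_id]] <- stats::setNames(-1, met)
  S <- stoichiometric_matrix(model)
  a <- as.numeric(model$reactions$id == sink_id)
  sol <- solve_lp(a, S, model$reactions$lower_bound,
                  model$reactions$upper_bound, maximize = TRUE)
  if (sol$status != "optimal") 0 else sum(a * sol$x)
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report>\n",
      "  dead-end metabolites:  ", nrow(x$dead_end_metabolites), "\n",
      "  blocked reactions:     ", length(x$blocked_reactions), "\n",
      "  disconnected biomass precursors: ",
      length(x$disconnected_biomass_precursors), "\n", sep = "")
  if (!is.na(x$diagnostic)) cat("  note: ", x$diagnostic, "\n", sep = "")
  invisible(x)
}

#' Suggest gap-filling candidates from EC-annotated target genes
#'
#' Every EC number present in the target-genome annotation but absent from
#' the draft model's reactions yields one candidate. Candidates whose
#' reaction template would close a reported gap — consume a never-consumed
#' dead end, produce a never-produced one, or produce a disconnected biomass
#' precursor — are ranked first; candidates without a template (unknown
#' stoichiometry) are ranked last. The candidate list feeds manual curation;
#' no automatic network modification is performed.
#'
#' @param model The draft [metabolic_model].
#' @param report A [find_gaps()] report.
#' @param annotations `data.frame` with columns `gene_id`, `ec` (one row per
#'   gene-EC assignment).
#' @param templates `data.frame` with columns `ec`, `equation` (e.g.
#'   `"A_c + 2 B_c -> C_c"`, `"<=>"` for reversible), `reversible`
#'   (logical); may be missing rows for some ECs.
#' @return `data.frame` with columns `ec`, `genes` (semicolon-separated
#'   supporting target genes), `equation`, `reversible`, `closes`
#'   (semicolon-separated gap ids the template would close), `rank`.
#' @export
suggest_candidates <- function(model, report, annotations, templates) {
  stopifnot(all(c("gene_id", "ec") %in% names(annotations)))
  if (is.null(templates)) {
    templates <- data.frame(ec = character(0), equation = character(0),
                            reversible = logical(0))
  }
  stopifnot(all(c("ec", "equation") %in% names(templates)))
  model_ecs <- stats::na.omit(model$reactions$ec)
  model_genes <- model$genes
  novel <- sort(setdiff(unique(annotations$ec), model_ecs))
  if (length(novel) == 0L) {
    return(data.frame(ec = character(0), genes = character(0),
                      equation = character(0), reversible = logical(0),
                      closes = character(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  never_consumed <- report$dead_end_metabolites$metabolite[
    report$dead_end_metabolites$role == "never-consumed"]
  never_produced <- report$dead_end_metabolites$metabolite[
    report$dead_end_metabolites$role == "never-produced"]
  disconnected <- report$disconnected_biomass_precursors

  out <- do.call(rbind, lapply(novel, function(ec) {
    genes <- setdiff(unique(annotations$gene_id[annotations$ec == ec]),
                     model_genes)
    ti <- match(ec, templates$ec)
    if (is.na(ti)) {
      return(data.frame(ec = ec, genes = paste(genes, collapse = ";"),
                        equation = NA_character_, reversible = NA,
                        closes = "", score = 2L, stringsAsFactors = FALSE))
    }
    eq <- parse_reaction_equation(templates$equation[ti])
    rev <- if (!is.null(templates$reversible)) isTRUE(templates$reversible[ti]) else eq$reversible
    st <- eq$stoichiometry
    consumes <- names(st)[st < 0 | rev]
    produces <- names(st)[st > 0 | rev]
    closes <- unique(c(intersect(consumes, never_consumed),
                       intersect(produces, c(never_produced, disconnected))))
    data.frame(ec = ec, genes = paste(genes, collapse = ";"),
               equation = templates$equation[ti], reversible = rev,
               closes = paste(closes, collapse = ";"),
               score = if (length(closes)) 0L else 1L, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$score, out$ec), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$score <- NULL
  rownames(out) <- NULL
  out
}

#' Parse a reaction equation string
#'
#' Understands `"A + 2 B -> C"` and `"A <=> B"`: metabolite ids separated by
#' `+`, optional leading numeric coefficients, `->` (irreversible) or `<=>`
#' (reversible) between the two sides. Either side may be empty.
#'
#' @param text Equation string.
#' @return List with `stoichiometry` (named numeric, substrates negative)
#'   and `reversible` (logical).
#' @export
parse_reaction_equation <- function(text) {
  reversible <- grepl("<=>", text, fixed = TRUE)
  sides <- strsplit(text, "<=>|->")[[1L]]
  if (length(sides) > 2L) stop("malformed reaction equation: ", text)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
    st <- numeric(0)
    for (t in terms) {
      parts <- strsplit(t, "[[:space:]]+")[[1L]]
      if (length(parts) == 2L && !is.na(suppressWarnings(as.numeric(parts[1L])))) {
        st[parts[2L]] <- sign * as.numeric(parts[1L])
      } else {
        st[t] <- sign * 1
      }
    }
    st
  }
  lhs <- parse_side(sides[1L], -1)
  rhs <- if (length(sides) == 2L) parse_side(sides[2L], +1) else numeric(0)
  both <- c(lhs, rhs)
  st <- tapply(both, names(both), sum)
  list(stoichiometry = stats::setNames(as.numeric(st), names(st)),
       reversible = reversible)
}

#' Write a gap report as TSV and JSON
#'
#' @param report A [find_gaps()] report.
#' @param tsv,json Output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_gap_report <- function(report, tsv = NULL, json = NULL) {
  part <- function(kind, id, detail = rep("", length(id))) {
    data.frame(kind = rep(kind, length(id)), id = id, detail = detail,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    part("dead_end", report$dead_end_metabolites$metabolite,
         report$dead_end_metabolites$role),
    part("blocked_reaction", report$blocked_reactions),
    part("disconnected_biomass_precursor",
         report$disconnected_biomass_precursors)
  )
  if (!is.null(tsv)) {
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(dead_end_metabolites = report$dead_end_metabolites,
           blocked_reactions = report$blocked_reactions,
           disconnected_biomass_precursors = report$disconnected_biomass_precursors,
           diagnostic = report$diagnostic),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
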