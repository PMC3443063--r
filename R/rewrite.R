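#' Rewrite a GPR from scaffold genes to target genes
#'
#' Replaces every scaffold-gene leaf by its mapped target gene(s): a leaf with
#' several candidate targets (a duplication or family expansion in the target)
#' becomes an OR over them; distinct scaffold leaves that map to one and the
#' same target gene (duplication/expansion in the scaffold) collapse to a
#' single leaf. A leaf with no mapping is dropped from an OR (some isozyme
#' alternative survives) but poisons its enclosing AND (the complex is
#' incomplete). If no complete alternative survives, the association is lost.
#'
#' The result is labelled with one of the evolutionary rewrite cases:
#' \describe{
#'   \item{M1}{gene loss; the whole association is unsatisfiable, `new_association` absent}
#'   \item{M3}{one-to-one orthologs throughout}
#'   \item{M4}{duplication in scaffold: two scaffold genes map onto one target gene}
#'   \item{M5}{expansion in scaffold: three or more scaffold genes onto one target}
#'   \item{M6}{duplication in target: one scaffold gene maps onto two targets}
#'   \item{M7}{expansion in target: one scaffold gene onto three or more targets}
#'   \item{mixed}{several of the above in one formula, or a partial loss}
#' }
#' (M2, gene gain, arises from [add_species_specific()], not from rewriting.)
#'
#' @param assoc A [gpr] tree.
#' @param map A consensus homolog map from [build_consensus()], or a plain
#'   named list mapping scaffold gene id to a character vector of target gene
#'   ids (an empty vector or missing name means no mapping).
#' @return An object of class `rewrite_result`: list with `new_association`
#'   ([gpr] or `NULL`), `case_label`, and `unresolved_genes` (scaffold genes
#'   with no mapping, reported for manual curation as possible loss of
#'   function).
#' @export
rewrite_gpr <- function(assoc, map) {
  stopifnot(is_gpr(assoc))
  targets_of <- homolog_lookup(map)

  unresolved <- character(0)
  events <- character(0)

  rec <- function(node) {
    if (node$op == "leaf") {
      tg <- targets_of(node$gene)
      if (length(tg) == 0L) {
        unresolved <<- union(unresolved, node$gene)
        return(NULL)
      }
      if (length(tg) == 2L) events <<- c(events, "M6")
      if (length(tg) > 2L) events <<- c(events, "M7")
      return(new_gpr_node("or", lapply(sort(tg), gpr_leaf)))
    }
    kids <- lapply(node$children, rec)
    if (node$op == "and") {
      if (any(vapply(kids, is.null, logical(1)))) return(NULL)
    } else {
      kids <- kids[!vapply(kids, is.null, logical(1))]
      if (length(kids) == 0L) return(NULL)
    }
    simplify_node(node$op, kids)
  }

  # collapse events: distinct scaffold leaves mapping to the same single target
  in_genes <- gpr_genes(assoc)
  single_target <- vapply(in_genes, function(g) {
    tg <- targets_of(g)
    if (length(tg) == 1L) tg else NA_character_
  }, character(1))
  tab <- table(single_target[!is.na(single_target)])
  events <- c(events,
              ifelse(tab[tab >= 2L] == 2L, "M4", "M5")[seq_len(sum(tab >= 2L))])

  out <- rec(assoc)
  if (is.null(out)) {
    case <- "M1"
  } else {
    ev <- unique(events)
    if (length(unresolved) > 0L) {
      case <- "mixed"
    } else if (length(ev) == 0L) {
      case <- "M3"
    } else if (length(ev) == 1L) {
      case <- ev
    } else {
      case <- "mixed"
    }
  }
  structure(
    list(new_association = out, case_label = case,
         unresolved_genes = sort(unresolved)),
    class = "rewrite_result"
  )
}

#' @export
print.rewrite_result <- function(x, ...) {
  cat("<rewrite_result> case ", x$case_label, ": ",
      if (is.null(x$new_association)) "(lost)" else gpr_to_string(x$new_association),
      "\n", sep = "")
  if (length(x$unresolved_genes)) {
    cat("  unresolved: ", paste(x$unresolved_genes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# flatten same-op children, merge duplicate leaves, apply absorption in ORs
simplify_node <- function(op, kids) {
  flat <- list()
  for (k in kids) {
    if (!is.null(k$op) && k$op == op) flat <- c(flat, k$children)
    else flat <- c(flat, list(k))
  }
  keys <- vapply(flat, gpr_to_string, character(1))
  flat <- flat[!duplicated(keys)]
  if (op == "or" && length(flat) > 1L) {
    # absorption: drop a child whose every minimal set contains some other
    # child's minimal set (A or (A and B) -> A)
    sets <- lapply(flat, minimal_gene_sets)
    absorbed <- vapply(seq_along(flat), function(a) {
      any(vapply(seq_along(flat), function(b) {
        if (a == b) return(FALSE)
        all(vapply(sets[[a]], function(sa) {
          any(vapply(sets[[b]], function(sb) all(sb %in% sa), logical(1)))
        }, logical(1))) && !identical(sets[[a]], sets[[b]])
      }, logical(1)))
    }, logical(1))
    flat <- flat[!absorbed]
  }
  new_gpr_node(op, flat)
}

# uniform lookup over consensus maps and plain named lists
homolog_lookup <- function(map) {
  if (inherits(map, "consensus_map")) {
    function(g) consensus_targets(map, g)
  } else if (is.list(map)) {
    function(g) {
      tg <- map[[g]]
      if (is.null(tg)) character(0) else unique(as.character(tg))
    }
  } else {
    stop("'map' must be a consensus_map or a named list of target gene vectors")
  }
}

#' Identity homolog map
#'
#' Maps every gene to itself; useful for identity projections and tests.
#'
#' @param genes Character vector of gene ids.
#' @return A named list usable as `map` in [rewrite_gpr()] and [project()].
#' @export
identity_map <- function(genes) {
  stats::setNames(as.list(genes), genes)
}
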