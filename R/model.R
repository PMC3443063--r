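#' Construct a compartmentalized metabolic model
#'
#' The central network object: reactions with signed stoichiometry over
#' metabolites (negative = substrate, positive = product), flux bounds in
#' mmol/gDW/h, optional GPR associations, compartments, and a biomass
#' objective reaction whose flux is the predicted growth rate.
#'
#' @param id Model identifier.
#' @param compartments `data.frame` with columns `id`, `name`.
#' @param metabolites `data.frame` with columns `id`, `name`, `compartment`,
#'   `boundary` (logical; boundary species are outside the mass balance).
#' @param reactions `data.frame` with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `category` (one of `"enzymatic"`, `"transport"`,
#'   `"exchange"`) and optionally `ec` (EC number or `NA`).
#' @param stoichiometry Named list (by reaction id) of named numeric vectors
#'   (by metabolite id) of signed coefficients.
#' @param gpr Named list (by reaction id) of [gpr] trees; reactions absent
#'   from the list (or `NULL`) have no gene association.
#' @param biomass_reaction Reaction id of the biomass objective, or `NA`.
#' @param genes Character vector of gene ids; defaults to the union of all
#'   GPR leaves.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions,
                            stoichiometry, gpr = list(),
                            biomass_reaction = NA_character_, genes = NULL) {
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$ec)) reactions$ec <- NA_character_
  if (is.null(metabolites$boundary)) metabolites$boundary <- FALSE
  gpr <- gpr[!vapply(gpr, is.null, logical(1))]
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(gpr, gpr_genes))))
    if (is.null(genes)) genes <- character(0)
  }
  m <- structure(
    list(id = id, compartments = compartments, metabolites = metabolites,
         reactions = reactions, stoichiometry = stoichiometry, gpr = gpr,
         genes = genes, biomass_reaction = biomass_reaction),
    class = "metabolic_model"
  )
  validate_metabolic_model(m)
  m
}

#' Check model invariants
#'
#' Verifies id uniqueness, referential integrity of compartments, metabolites
#' and genes, bound ordering, non-empty stoichiometries, and the structural
#' constraints on exchange reactions.
#'
#' @param m A [metabolic_model].
#' @return `m`, invisibly; stops with a message on the first violation.
#' @export
validate_metabolic_model <- function(m) {
  stopifnot(inherits(m, "metabolic_model"))
  if (anyDuplicated(m$compartments$id)) stop("duplicate compartment ids")
  if (any(!nzchar(m$compartments$id))) stop("empty compartment id")
  if (anyDuplicated(m$metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(m$reactions$id)) stop("duplicate reaction ids")
  bad <- setdiff(m$metabolites$compartment, m$compartments$id)
  if (length(bad)) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  if (any(m$reactions$lower_bound > m$reactions$upper_bound)) {
    stop("lower_bound > upper_bound in reaction(s): ",
         paste(m$reactions$id[m$reactions$lower_bound > m$reactions$upper_bound],
               collapse = ", "))
  }
  if (!all(m$reactions$category %in% c("enzymatic", "transport", "exchange"))) {
    stop("invalid reaction category")
  }
  if (!setequal(names(m$stoichiometry), m$reactions$id) ||
      length(m$stoichiometry) != nrow(m$reactions)) {
    stop("stoichiometry list does not match reaction ids")
  }
  for (rid in m$reactions$id) {
    st <- m$stoichiometry[[rid]]
    if (length(st) == 0L) stop("empty stoichiometry in reaction ", rid)
    miss <- setdiff(names(st), m$metabolites$id)
    if (length(miss)) {
      stop("reaction ", rid, " references unknown metabolite(s): ",
           paste(miss, collapse = ", "))
    }
  }
  ex <- m$reactions$id[m$reactions$category == "exchange"]
  bnd <- m$metabolites$id[m$metabolites$boundary]
  for (rid in ex) {
    nb <- setdiff(names(m$stoichiometry[[rid]]), bnd)
    if (length(nb) != 1L) {
      stop("exchange reaction ", rid, " must touch exactly one non-boundary metabolite")
    }
  }
  gg <- setdiff(unlist(lapply(m$gpr, gpr_genes)), m$genes)
  if (length(gg)) stop("GPR gene(s) not in model genes: ", paste(gg, collapse = ", "))
  extra <- setdiff(names(m$gpr), m$reactions$id)
  if (length(extra)) stop("GPR for unknown reaction(s): ", paste(extra, collapse = ", "))
  if (!is.na(m$biomass_reaction) && !(m$biomass_reaction %in% m$reactions$id)) {
    stop("biomass reaction ", m$biomass_reaction, " not found")
  }
  invisible(m)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  reactions:    ", nrow(x$reactions), "\n",
      "  metabolites:  ", nrow(x$metabolites), "\n",
      "  genes:        ", length(x$genes), "\n",
      "  compartments: ", nrow(x$compartments), "\n",
      "  biomass:      ", x$biomass_reaction, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix
#'
#' @param m A [metabolic_model].
#' @param drop_boundary Drop rows of boundary metabolites (they are outside
#'   the steady-state mass balance). Default `TRUE`.
#' @return Dense numeric matrix, metabolites x reactions.
#' @export
stoichiometric_matrix <- function(m, drop_boundary = TRUE) {
  mets <- m$metabolites$id
  if (drop_boundary) mets <- m$metabolites$id[!m$metabolites$boundary]
  S <- matrix(0, nrow = length(mets), ncol = nrow(m$reactions),
              dimnames = list(mets, m$reactions$id))
  for (rid in m$reactions$id) {
    st <- m$stoichiometry[[rid]]
    keep <- names(st) %in% mets
    if (any(keep)) S[names(st)[keep], rid] <- st[keep]
  }
  S
}

#' Classify a reaction's category from its structure
#'
#' Used when annotations carry no category (e.g. on SBML read): a reaction is
#' an `exchange` if it touches a boundary metabolite (with a single
#' non-boundary partner) or consumes/produces a single metabolite one-sidedly;
#' a `transport` if the same metabolite species occurs in two
#' compartments among its participants; otherwise `enzymatic`. Species
#' identity across compartments is taken from the metabolite id with its
#' compartment suffix (`_<compartment>`) stripped, falling back to the name.
#'
#' @param stoich Named numeric stoichiometry vector.
#' @param metabolites The model's metabolite `data.frame`.
#' @return `"exchange"`, `"transport"` or `"enzymatic"`.
#' @export
classify_reaction_category <- function(stoich, metabolites) {
  idx <- match(names(stoich), metabolites$id)
  nonb <- names(stoich)[!metabolites$boundary[idx]]
  if (any(metabolites$boundary[idx]) && length(nonb) == 1L) return("exchange")
  if ((all(stoich > 0) || all(stoich < 0)) && length(stoich) == 1L) return("exchange")
  comp <- metabolites$compartment[idx]
  key <- sub(paste0("_(", paste(unique(metabolites$compartment), collapse = "|"), ")$"),
             "", names(stoich))
  if (length(unique(comp)) >= 2L && anyDuplicated(key)) return("transport")
  "enzymatic"
}

#' Census of a metabolic model
#'
#' Counts reactions, metabolites, genes and compartments and partitions the
#' reactions into five classes: transport with/without a gene association,
#' exchanges with the media, and enzymatic with/without a gene association.
#' Percentages are shares of total reactions, rounded to one decimal.
#'
#' @param m A [metabolic_model].
#' @return An object of class `model_census` with fields `n_reactions`,
#'   `n_metabolites`, `n_genes`, `n_compartments`, `counts` (named integer
#'   vector over the five classes) and `percentages`.
#' @export
census <- function(m) {
  validate_metabolic_model(m)
  has_gpr <- m$reactions$id %in% names(m$gpr)
  cat5 <- ifelse(m$reactions$category == "exchange", "exchange",
          ifelse(m$reactions$category == "transport",
                 ifelse(has_gpr, "transport_with_gpr", "transport_without_gpr"),
                 ifelse(has_gpr, "enzymatic_with_gpr", "enzymatic_without_gpr")))
  lv <- census_classes()
  counts <- stats::setNames(as.integer(table(factor(cat5, levels = lv))), lv)
  structure(
    list(n_reactions = nrow(m$reactions),
         n_metabolites = nrow(m$metabolites),
         n_genes = length(m$genes),
         n_compartments = nrow(m$compartments),
         counts = counts,
         percentages = census_shares(counts)),
    class = "model_census"
  )
}

census_classes <- function() {
  c("transport_with_gpr", "transport_without_gpr", "exchange",
    "enzymatic_with_gpr", "enzymatic_without_gpr")
}

#' Category shares as percentages
#'
#' @param counts Named integer vector of reaction counts per class.
#' @return Named numeric vector: `count / total * 100` rounded to one
#'   decimal; all zero when the total is zero.
#' @export
census_shares <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(stats::setNames(rep(0, length(counts)), names(counts)))
  round(counts / total * 100, 1)
}

#' Format census shares for a human-readable report
#'
#' A share is printed to one decimal, except that a share of at least 5% whose
#' one-decimal value lies within 0.1 of a whole number is printed as that
#' integer (so 6.9 and 7.0 both print as \code{7\%}, while 14.3 keeps its
#' decimal). Machine-readable outputs always keep one decimal.
#'
#' @param percentages Named numeric vector from [census_shares()].
#' @return Named character vector like `"52.7%"`.
#' @export
format_census_shares <- function(percentages) {
  out <- vapply(percentages, function(p) {
    if (p >= 5 && abs(p - round(p)) <= 0.1) {
      sprintf("%d%%", as.integer(round(p)))
    } else {
      sprintf("%.1f%%", p)
    }
  }, character(1))
  stats::setNames(out, names(percentages))
}

#' @export
print.model_census <- function(x, ...) {
  cat("<model_census>\n",
      "  reactions: ", x$n_reactions,
      "  metabolites: ", x$n_metabolites,
      "  genes: ", x$n_genes,
      "  compartments: ", x$n_compartments, "\n", sep = "")
  shares <- format_census_shares(x$percentages)
  for (k in names(x$counts)) {
    cat(sprintf("  %-24s %5d (%s)\n", k, x$counts[[k]], shares[[k]]))
  }
  invisible(x)
}

#' Write a census as delimited text and JSON
#'
#' @param cens A [census()] result.
#' @param tsv,json Output file paths (either may be `NULL` to skip).
#' @return `cens`, invisibly.
#' @export
write_census <- function(cens, tsv = NULL, json = NULL) {
  df <- data.frame(class = names(cens$counts),
                   count = as.integer(cens$counts),
                   percentage = as.numeric(cens$percentages),
                   printed = unname(format_census_shares(cens$percentages)),
                   stringsAsFactors = FALSE)
  if (!is.null(tsv)) {
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(n_reactions = cens$n_reactions, n_metabolites = cens$n_metabolites,
           n_genes = cens$n_genes, n_compartments = cens$n_compartments,
           classes = df),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(cens)
}

#' Compare two models up to isomorphism
#'
#' Two models are isomorphic when they have the same reaction, metabolite and
#' compartment ids, identical stoichiometries and bounds, and GPRs equal as
#' truth tables (compared by minimal gene sets).
#'
#' @param a,b [metabolic_model] objects.
#' @return Logical scalar.
#' @export
models_isomorphic <- function(a, b) {
  if (!setequal(a$reactions$id, b$reactions$id)) return(FALSE)
  if (!setequal(a$metabolites$id, b$metabolites$id)) return(FALSE)
  if (!setequal(a$compartments$id, b$compartments$id)) return(FALSE)
  ia <- match(a$reactions$id, b$reactions$id)
  if (any(a$reactions$lower_bound != b$reactions$lower_bound[ia]) ||
      any(a$reactions$upper_bound != b$reactions$upper_bound[ia])) {
    return(FALSE)
  }
  for (rid in a$reactions$id) {
    sa <- a$stoichiometry[[rid]]
    sb <- b$stoichiometry[[rid]]
    sa <- sa[order(names(sa))]
    sb <- sb[order(names(sb))]
    if (!identical(names(sa), names(sb)) || any(sa != sb)) return(FALSE)
    if (!gpr_equivalent(a$gpr[[rid]], b$gpr[[rid]])) return(FALSE)
  }
  TRUE
}
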