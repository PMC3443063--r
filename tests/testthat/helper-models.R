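# Compact builder for small hand-written models. `rxns` is a named list:
# each element list(stoich = named numeric, lb = , ub = , gpr = string|NULL,
# category = NULL for auto-classification). Metabolites are created on the
# fly; compartment is inferred from a trailing "_<comp>" id suffix (default
# cytosol "c"), ids ending in "_e" are extracellular.
toy_model <- function(rxns, biomass = NA_character_, id = "toy",
                      boundary = character(0)) {
  met_ids <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  comp_of <- function(mid) {
    s <- regmatches(mid, regexpr("_([a-z0-9]+)$", mid))
    if (length(s)) sub("^_", "", s) else "c"
  }
  comps <- unique(vapply(met_ids, comp_of, character(1)))
  metabolites <- data.frame(id = met_ids, name = met_ids,
                            compartment = vapply(met_ids, comp_of, character(1)),
                            boundary = met_ids %in% boundary,
                            stringsAsFactors = FALSE)
  gpr <- list()
  reactions <- data.frame(id = character(0), name = character(0),
                          lower_bound = numeric(0), upper_bound = numeric(0),
                          category = character(0), stringsAsFactors = FALSE)
  stoich <- list()
  for (rid in names(rxns)) {
    r <- rxns[[rid]]
    lb <- if (is.null(r$lb)) 0 else r$lb
    ub <- if (is.null(r$ub)) 1000 else r$ub
    category <- if (is.null(r$category)) {
      classify_reaction_category(r$stoich, metabolites)
    } else r$category
    reactions[nrow(reactions) + 1, ] <- list(rid, rid, lb, ub, category)
    stoich[[rid]] <- r$stoich
    if (!is.null(r$gpr)) gpr[[rid]] <- parse_gpr(r$gpr)
  }
  metabolic_model(id = id,
                  compartments = data.frame(id = comps, name = comps,
                                            stringsAsFactors = FALSE),
                  metabolites = metabolites, reactions = reactions,
                  stoichiometry = stoich, gpr = gpr,
                  biomass_reaction = biomass)
}

# Linear chain: EX (uptake <= 10) -> A -> B -> biomass, used in several tests
chain_model <- function() {
  toy_model(list(
    EX_A = list(stoich = c(A_c = 1), lb = 0, ub = 10, category = "exchange"),
    R1 = list(stoich = c(A_c = -1, B_c = 1), gpr = "G1"),
    BIOMASS = list(stoich = c(B_c = -1, BIO_c = 1), category = "enzymatic"),
    EX_BIO = list(stoich = c(BIO_c = -1), category = "exchange")
  ), biomass = "BIOMASS")
}
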