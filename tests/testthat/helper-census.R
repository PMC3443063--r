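# Synthetic model with a prescribed reaction-category composition, used to
# exercise census() at the published model's scale. Vectorized construction:
# exchanges consume a lone external metabolite, transports move one species
# e -> c, enzymatic reactions convert between cytosolic metabolites; the
# "_with_gpr" classes carry one gene each.
make_category_model <- function(transport_with_gpr, transport_without_gpr,
                                exchange, enzymatic_with_gpr,
                                enzymatic_without_gpr) {
  n_tr <- transport_with_gpr + transport_without_gpr
  n_en <- enzymatic_with_gpr + enzymatic_without_gpr
  rid <- c(sprintf("TRG_%04d", seq_len(transport_with_gpr)),
           sprintf("TRS_%04d", seq_len(transport_without_gpr)),
           sprintf("EXC_%04d", seq_len(exchange)),
           sprintf("ENG_%04d", seq_len(enzymatic_with_gpr)),
           sprintf("ENS_%04d", seq_len(enzymatic_without_gpr)))
  category <- rep(c("transport", "exchange", "enzymatic"),
                  c(n_tr, exchange, n_en))
  tr_e <- sprintf("T%04d_e", seq_len(n_tr))
  tr_c <- sprintf("T%04d_c", seq_len(n_tr))
  ex_e <- sprintf("E%04d_e", seq_len(exchange))
  en_a <- sprintf("A%04d_c", seq_len(n_en))
  en_b <- sprintf("B%04d_c", seq_len(n_en))
  stoich <- c(
    mapply(function(a, b) stats::setNames(c(-1, 1), c(a, b)),
           tr_e, tr_c, SIMPLIFY = FALSE),
    lapply(ex_e, function(a) stats::setNames(-1, a)),
    mapply(function(a, b) stats::setNames(c(-1, 1), c(a, b)),
           en_a, en_b, SIMPLIFY = FALSE)
  )
  names(stoich) <- rid
  gpr <- lapply(seq_len(transport_with_gpr + enzymatic_with_gpr), function(i) {
    gpr_leaf(sprintf("G%04d", i))
  })
  names(gpr) <- c(rid[seq_len(transport_with_gpr)],
                  sprintf("ENG_%04d", seq_len(enzymatic_with_gpr)))
  mets <- unique(c(tr_e, tr_c, ex_e, en_a, en_b))
  metabolic_model(
    id = "synthetic_census_model",
    compartments = data.frame(id = c("e", "c"),
                              name = c("extracellular", "cytosol")),
    metabolites = data.frame(id = mets, name = mets,
                             compartment = ifelse(grepl("_e$", mets), "e", "c"),
                             boundary = FALSE, stringsAsFactors = FALSE),
    reactions = data.frame(id = rid, name = rid, lower_bound = 0,
                           upper_bound = 1000, category = category,
                           stringsAsFactors = FALSE),
    stoichiometry = stoich,
    gpr = gpr
  )
}
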