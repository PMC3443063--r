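test_that("identity projection is a model isomorphism with nothing lost", {
  sp <- fixture_spec(seed = 4, n_linear_pathways = 4, pathway_length = 3)
  m <- make_scaffold(sp)
  pr <- project(m, identity_map(m$genes))
  expect_true(models_isomorphic(m, pr$model))
  expect_length(pr$report$lost, 0)
  expect_length(pr$report$unresolved_genes, 0)
  expect_true(all(pr$report$conserved$case == "M3"))
})

test_that("an unmapped essential gene loses its reaction (planted loss)", {
  m <- toy_model(list(
    EX = list(stoich = c(S_c = 1), lb = 0, ub = 10, category = "exchange"),
    R1 = list(stoich = c(S_c = -1, P_c = 1), gpr = "GA and GB"),
    R2 = list(stoich = c(P_c = -1, Q_c = 1), gpr = "GC"),
    BIOMASS = list(stoich = c(Q_c = -1, BIO_c = 1), category = "enzymatic"),
    EXB = list(stoich = c(BIO_c = -1), category = "exchange")
  ), biomass = "BIOMASS")
  map <- list(GA = "tA", GC = "tC")  # GB unmapped: AND-essential
  pr <- project(m, map)
  expect_identical(pr$report$lost, "R1")
  expect_identical(pr$report$unresolved_genes, "GB")
  expect_false("R1" %in% pr$model$reactions$id)
  # partition: every GPR-bearing reaction is conserved or lost
  n_gpr <- length(m$gpr)
  expect_identical(nrow(pr$report$conserved) + length(pr$report$lost), n_gpr)
})

test_that("a family expansion yields a wide OR in the conserved reaction", {
  m <- toy_model(list(
    EX = list(stoich = c(S_c = 1), lb = 0, ub = 10, category = "exchange"),
    R1 = list(stoich = c(S_c = -1, P_c = 1), gpr = "GA"),
    BIOMASS = list(stoich = c(P_c = -1, BIO_c = 1), category = "enzymatic"),
    EXB = list(stoich = c(BIO_c = -1), category = "exchange")
  ), biomass = "BIOMASS")
  fam <- paste0("t", 1:6)
  pr <- project(m, list(GA = fam))
  expect_identical(pr$report$conserved$case[pr$report$conserved$reaction == "R1"],
                   "M7")
  expect_identical(minimal_gene_sets(pr$model$gpr$R1), as.list(fam))
})

test_that("conservation matches GPR satisfiability under the mapped targets", {
  set.seed(31)
  sp <- fixture_spec(seed = 31, n_linear_pathways = 4, pathway_length = 3,
                     event_mix = c(loss = 0.3, one_to_one = 0.4,
                                   dup_in_scaffold = 0.1,
                                   expansion_in_scaffold = 0.05,
                                   dup_in_target = 0.1,
                                   expansion_in_target = 0.05))
  m <- make_scaffold(sp)
  om <- make_ortholog_maps(m, sp)
  cons <- build_consensus(om$maps)
  pr <- project(m, cons)
  for (rid in names(m$gpr)) {
    mapped_genes <- Filter(function(g) length(consensus_targets(cons, g)) > 0,
                           gpr_genes(m$gpr[[rid]]))
    should_conserve <- oracle_eval_gpr_string(gpr_to_string(m$gpr[[rid]]),
                                              mapped_genes)
    expect_identical(rid %in% pr$report$conserved$reaction, should_conserve,
                     info = rid)
    expect_identical(rid %in% pr$report$lost, !should_conserve, info = rid)
  }
})

test_that("spontaneous and exchange reactions follow their keep options", {
  sp <- fixture_spec(seed = 4, n_linear_pathways = 2, pathway_length = 2)
  m <- make_scaffold(sp)
  pr <- project(m, identity_map(m$genes),
                projection_options(keep_spontaneous = FALSE,
                                   keep_exchanges = FALSE))
  spont <- setdiff(m$reactions$id[m$reactions$category != "exchange"],
                   c(names(m$gpr), m$biomass_reaction))
  exch <- m$reactions$id[m$reactions$category == "exchange"]
  expect_setequal(pr$report$dropped, c(spont, exch))
  # biomass is always retained
  expect_true(m$biomass_reaction %in% pr$model$reactions$id)
})

test_that("curation overrides force-retain and force-drop reactions", {
  m <- toy_model(list(
    EX = list(stoich = c(S_c = 1), lb = 0, ub = 10, category = "exchange"),
    R1 = list(stoich = c(S_c = -1, P_c = 1), gpr = "GA"),
    R2 = list(stoich = c(P_c = -1, Q_c = 1), gpr = "GB"),
    BIOMASS = list(stoich = c(Q_c = -1, BIO_c = 1), category = "enzymatic"),
    EXB = list(stoich = c(BIO_c = -1), category = "exchange")
  ), biomass = "BIOMASS")
  cur <- data.frame(reaction_id = c("R1", "R2"),
                    verdict = c("Retained", "Lost"),
                    stringsAsFactors = FALSE)
  pr <- project(m, list(GB = "tB"), projection_options(curation = cur))
  expect_true("R1" %in% pr$model$reactions$id)   # retained despite no mapping
  expect_null(pr$model$gpr$R1)                   # without gene association
  expect_identical(pr$report$lost, "R2")         # dropped despite mapping
})

test_that("projection requires a biomass reaction", {
  m <- chain_model()
  m$biomass_reaction <- NA_character_
  expect_error(project(m, list()), "biomass")
})

test_that("species-specific gains extend the model and the census", {
  m <- chain_model()
  n0 <- census(m)$n_reactions
  m2 <- add_species_specific(m, list(
    list(id = "R_gain", stoich = NULL,
         stoichiometry = c(B_c = -1, NEW_c = 1),
         gpr = "TG1 and TG2",
         metabolite_compartments = c(NEW_c = "c"))
  ))
  expect_identical(census(m2)$n_reactions, n0 + 1L)
  expect_true("NEW_c" %in% m2$metabolites$id)     # auto-created metabolite
  expect_true(all(c("TG1", "TG2") %in% m2$genes))
  expect_silent(validate_metabolic_model(m2))
})

test_that("id collisions on insertion are rejected by name", {
  m <- chain_model()
  expect_error(
    add_species_specific(m, list(list(id = "R1", stoichiometry = c(A_c = -1)))),
    "R1")
})

test_that("a batch of new transports is recorded as gained in the report", {
  sp <- fixture_spec(seed = 9, n_linear_pathways = 3, pathway_length = 2)
  m <- make_scaffold(sp)
  pr <- project(m, identity_map(m$genes))
  adds <- lapply(1:13, function(i) {
    list(id = sprintf("TNEW_%02d", i),
         stoichiometry = stats::setNames(c(-1, 1),
                                         c("PREC_c", sprintf("PX%02d_x1", i))),
         category = "transport",
         metabolite_compartments = stats::setNames("x1", sprintf("PX%02d_x1", i)))
  })
  res <- add_species_specific(pr$model, adds, report = pr$report)
  expect_length(res$report$gained, 13)
  expect_silent(validate_metabolic_model(res$model))
})

test_that("biomass GC re-balancing conserves the precursor total", {
  sp <- fixture_spec(seed = 4, n_linear_pathways = 2, pathway_length = 2)
  m <- make_scaffold(sp)
  orig <- m$stoichiometry$BIOMASS
  pre <- c("dATP_c", "dCTP_c", "dGTP_c", "dTTP_c")
  total0 <- sum(abs(orig[pre]))

  m2 <- adjust_biomass(m, biomass_adjustment(gc_content = 0.49,
                                             genome_length = 20.5e6))
  st <- m2$stoichiometry$BIOMASS
  expect_equal(sum(abs(st[pre])), total0, tolerance = 1e-9)
  expect_equal(unname(st[["dGTP_c"]]), unname(st[["dCTP_c"]]))
  expect_equal(unname(st[["dATP_c"]]), unname(st[["dTTP_c"]]))
  expect_gt(abs(st[["dATP_c"]]), abs(st[["dGTP_c"]]))  # AT-rich at GC 0.49
  # untouched coefficients stay put
  others <- setdiff(names(orig), pre)
  expect_identical(st[others], orig[others])
})

test_that("equal GC content gives four equal precursor coefficients", {
  sp <- fixture_spec(seed = 4, n_linear_pathways = 2, pathway_length = 2)
  m <- make_scaffold(sp)
  m2 <- adjust_biomass(m, biomass_adjustment(0.5, 1e7))
  st <- m2$stoichiometry$BIOMASS[c("dATP_c", "dCTP_c", "dGTP_c", "dTTP_c")]
  expect_true(all(abs(st - st[1]) < 1e-12))
})

test_that("precursor demand scales proportionally with the DNA mass fraction", {
  sp <- fixture_spec(seed = 4, n_linear_pathways = 2, pathway_length = 2)
  m <- make_scaffold(sp)
  len <- 1e7
  per_bp <- 2e-8
  m1 <- adjust_biomass(m, biomass_adjustment(0.4, len, dna_mass_fraction = len * per_bp))
  m2 <- adjust_biomass(m, biomass_adjustment(0.4, 2 * len, dna_mass_fraction = 2 * len * per_bp))
  pre <- c("dATP_c", "dCTP_c", "dGTP_c", "dTTP_c")
  expect_equal(m2$stoichiometry$BIOMASS[pre],
               2 * m1$stoichiometry$BIOMASS[pre], tolerance = 1e-12)
})

test_that("missing precursor ids are reported by name", {
  m <- chain_model()
  expect_error(adjust_biomass(m, biomass_adjustment(0.4, 1e7)), "dATP_c")
})
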