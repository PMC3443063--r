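test_that("a terminal metabolite is a never-consumed dead end", {
  m <- toy_model(list(
    EX = list(stoich = c(A_c = 1), lb = 0, ub = 10, category = "exchange"),
    R1 = list(stoich = c(A_c = -1, B_c = 1)),
    R2 = list(stoich = c(B_c = -1, C_c = 1)),
    BIOMASS = list(stoich = c(B_c = -1, BIO_c = 1), category = "enzymatic"),
    EXB = list(stoich = c(BIO_c = -1), category = "exchange")
  ), biomass = "BIOMASS")
  rep <- find_gaps(m)
  expect_true("C_c" %in% rep$dead_end_metabolites$metabolite)
  expect_identical(
    rep$dead_end_metabolites$role[rep$dead_end_metabolites$metabolite == "C_c"],
    "never-consumed")
})

test_that("a consumed-but-never-produced metabolite is flagged", {
  m <- toy_model(list(
    EX = list(stoich = c(A_c = 1), lb = 0, ub = 10, category = "exchange"),
    R1 = list(stoich = c(A_c = -1, X_c = -1, B_c = 1)),  # X never produced
    BIOMASS = list(stoich = c(B_c = -1, BIO_c = 1), category = "enzymatic"),
    EXB = list(stoich = c(BIO_c = -1), category = "exchange")
  ), biomass = "BIOMASS")
  rep <- find_gaps(m)
  expect_identical(
    rep$dead_end_metabolites$role[rep$dead_end_metabolites$metabolite == "X_c"],
    "never-produced")
})

test_that("a fully connected growing model has an empty gap report", {
  sp <- fixture_spec(seed = 12, n_linear_pathways = 2, pathway_length = 2,
                     n_compartments = 2)
  m <- make_scaffold(sp)
  rep <- find_gaps(m)
  expect_identical(nrow(rep$dead_end_metabolites), 0L)
  expect_length(rep$blocked_reactions, 0)
  expect_length(rep$disconnected_biomass_precursors, 0)
  expect_true(is.na(rep$diagnostic))
})

test_that("deleting a reaction from a linear biomass path blocks downstream flux", {
  sp <- fixture_spec(seed = 12, n_linear_pathways = 1, pathway_length = 3,
                     n_compartments = 2)
  m <- make_scaffold(sp)
  # remove the middle chain step
  drop <- "R_1_2"
  keep <- setdiff(m$reactions$id, drop)
  m$reactions <- m$reactions[m$reactions$id %in% keep, ]
  m$stoichiometry <- m$stoichiometry[keep]
  m$gpr <- m$gpr[intersect(names(m$gpr), keep)]
  rep <- find_gaps(m)
  # everything is blocked: the only carbon path is cut
  expect_true(all(c("R_1_1", "R_1_3", "BIOMASS") %in% rep$blocked_reactions))
  expect_true("PREC_c" %in% rep$disconnected_biomass_precursors)
})

test_that("structural dead ends agree with a brute-force stoichiometry scan", {
  for (seed in c(3, 13)) {
    sp <- fixture_spec(seed = seed, n_linear_pathways = 3, pathway_length = 2)
    m <- make_scaffold(sp)
    # randomly drop two reactions to create gaps
    set.seed(seed)
    drop <- sample(setdiff(m$reactions$id, "BIOMASS"), 2)
    keep <- setdiff(m$reactions$id, drop)
    m$reactions <- m$reactions[m$reactions$id %in% keep, ]
    m$stoichiometry <- m$stoichiometry[keep]
    m$gpr <- m$gpr[intersect(names(m$gpr), keep)]
    rep <- find_gaps(m)

    S <- stoichiometric_matrix(m)
    lb <- m$reactions$lower_bound
    ub <- m$reactions$upper_bound
    for (met in rownames(S)) {
      row <- S[met, ]
      can_produce <- any((row > 0 & ub > 0) | (row < 0 & lb < 0))
      can_consume <- any((row < 0 & ub > 0) | (row > 0 & lb < 0))
      flagged <- rep$dead_end_metabolites$metabolite == met
      if (can_produce && !can_consume) {
        expect_identical(rep$dead_end_metabolites$role[flagged], "never-consumed")
      } else if (can_consume && !can_produce) {
        expect_identical(rep$dead_end_metabolites$role[flagged], "never-produced")
      } else {
        expect_false(any(flagged))
      }
    }
  }
})

test_that("candidates are ranked by whether they close a reported gap", {
  m <- toy_model(list(
    EX = list(stoich = c(A_c = 1), lb = 0, ub = 10, category = "exchange"),
    R1 = list(stoich = c(A_c = -1, B_c = 1), gpr = "G1"),
    BIOMASS = list(stoich = c(B_c = -1, BIO_c = 1), category = "enzymatic"),
    EXB = list(stoich = c(BIO_c = -1), category = "exchange")
  ), biomass = "BIOMASS")
  m$reactions$ec[m$reactions$id == "R1"] <- "1.1.1.1"
  # plant a dead end: D_c consumed by nothing
  m <- add_species_specific(m, list(
    list(id = "R2", stoichiometry = c(B_c = -1, D_c = 1),
         metabolite_compartments = c(D_c = "c"))))
  rep <- find_gaps(m)
  expect_true("D_c" %in% rep$dead_end_metabolites$metabolite)

  annotations <- data.frame(
    gene_id = c("TGx", "TGy", "TGz"),
    ec = c("2.2.2.2", "3.3.3.3", "1.1.1.1"),  # 1.1.1.1 already in draft
    stringsAsFactors = FALSE)
  templates <- data.frame(
    ec = "2.2.2.2", equation = "D_c -> E_c", reversible = FALSE,
    stringsAsFactors = FALSE)
  cand <- suggest_candidates(m, rep, annotations, templates)
  expect_identical(cand$ec, c("2.2.2.2", "3.3.3.3"))  # covered EC excluded
  expect_identical(cand$rank, 1:2)
  expect_identical(cand$closes[1], "D_c")             # gap-closing first
  expect_true(is.na(cand$equation[2]))                # no template: last
})

test_that("fully covered annotations yield no candidates", {
  m <- chain_model()
  m$reactions$ec[m$reactions$id == "R1"] <- "1.1.1.1"
  rep <- find_gaps(m)
  cand <- suggest_candidates(m, rep,
                             data.frame(gene_id = "TG1", ec = "1.1.1.1"),
                             NULL)
  expect_identical(nrow(cand), 0L)
})

test_that("applying additive candidates never blocks an unblocked reaction", {
  sp <- fixture_spec(seed = 12, n_linear_pathways = 1, pathway_length = 3,
                     n_compartments = 2)
  m <- make_scaffold(sp)
  drop <- "R_1_2"
  keep <- setdiff(m$reactions$id, drop)
  m$reactions <- m$reactions[m$reactions$id %in% keep, ]
  m$stoichiometry <- m$stoichiometry[keep]
  m$gpr <- m$gpr[intersect(names(m$gpr), keep)]
  before <- find_gaps(m)
  unblocked_before <- setdiff(m$reactions$id, before$blocked_reactions)
  # apply a candidate that repairs the cut
  m2 <- add_species_specific(m, list(
    list(id = "R_fix", stoichiometry = c(M1_1_c = -1, M1_2_c = 1),
         gpr = "TG_fix")))
  after <- find_gaps(m2)
  expect_true(all(unblocked_before %in%
                    setdiff(m2$reactions$id, after$blocked_reactions)))
  # and the repair unblocks the chain
  expect_false("BIOMASS" %in% after$blocked_reactions)
})

test_that("gap reports serialize to TSV and JSON", {
  sp <- fixture_spec(seed = 12, n_linear_pathways = 2, pathway_length = 2)
  m <- make_scaffold(sp)
  rep <- find_gaps(m)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_gap_report(rep, tsv = tsv, json = js)
  expect_true(file.exists(tsv))
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_length(j$blocked_reactions, 0)
})

test_that("reaction equations parse with coefficients and reversibility", {
  eq <- parse_reaction_equation("A_c + 2 B_c -> C_c")
  expect_identical(sort(names(eq$stoichiometry)), c("A_c", "B_c", "C_c"))
  expect_identical(unname(eq$stoichiometry[c("A_c", "B_c", "C_c")]), c(-1, -2, 1))
  expect_false(eq$reversible)
  expect_true(parse_reaction_equation("A_c <=> B_c")$reversible)
})
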