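test_that("FBA on a linear chain saturates the uptake bound", {
  sol <- fba(chain_model())
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-9)
})

test_that("an objective downstream of a closed reaction is zero", {
  m <- chain_model()
  m$reactions$lower_bound[m$reactions$id == "R1"] <- 0
  m$reactions$upper_bound[m$reactions$id == "R1"] <- 0
  sol <- fba(m)
  expect_equal(sol$objective, 0, tolerance = 1e-9)
})

test_that("optimal solutions satisfy mass balance and bounds within 1e-6", {
  for (seed in c(2, 5)) {
    sp <- fixture_spec(seed = seed, n_linear_pathways = 4, pathway_length = 3)
    m <- make_scaffold(sp)
    sol <- fba(m)
    expect_identical(sol$status, "optimal")
    S <- stoichiometric_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    expect_true(all(sol$fluxes >= m$reactions$lower_bound - 1e-6))
    expect_true(all(sol$fluxes <= m$reactions$upper_bound + 1e-6))
  }
})

test_that("FBA optimum equals the vertex-enumeration oracle on toy networks", {
  set.seed(17)
  # a branched network: uptake splits into two routes with different yields
  nets <- list()
  nets$branch <- list(
    S = matrix(c(
      #  EX  Ra  Rb  Rc  OUT
      1, -1, -1, 0, 0,    # A
      0, 1, 0, -1, 0,     # B
      0, 0, 2, -1, 0,     # C (route b doubles)
      0, 0, 0, 1, -1      # P
    ), nrow = 4, byrow = TRUE),
    lb = c(0, 0, 0, 0, 0), ub = c(10, 10, 10, 10, 100), obj = 5
  )
  nets$reversible <- list(
    S = matrix(c(
      1, -1, 1, 0,
      0, 1, -1, -1
    ), nrow = 2, byrow = TRUE),
    lb = c(0, -5, 0, 0), ub = c(8, 10, 3, 100), obj = 4
  )
  # random small networks (up to 6 reactions)
  for (k in 1:6) {
    n <- sample(4:6, 1)
    mm <- sample(2:3, 1)
    S <- matrix(sample(c(-1, 0, 1), mm * n, replace = TRUE, prob = c(.35, .3, .35)),
                mm, n)
    lb <- ifelse(runif(n) < 0.3, -5, 0)
    ub <- rep(10, n)
    nets[[paste0("rand", k)]] <- list(S = S, lb = lb, ub = ub, obj = n)
  }
  for (nm in names(nets)) {
    net <- nets[[nm]]
    got <- lp_bounded(as.numeric(seq_len(ncol(net$S)) == net$obj), net$S,
                      rep(0, nrow(net$S)), net$lb, net$ub)
    want <- oracle_fba_vertex(net$S, net$lb, net$ub, net$obj)
    expect_identical(got$status, "optimal", info = nm)
    expect_equal(got$objective, want, tolerance = 1e-7, info = nm)
  }
})

test_that("the FBA objective is invariant under reaction permutation", {
  sp <- fixture_spec(seed = 6, n_linear_pathways = 3, pathway_length = 3)
  m <- make_scaffold(sp)
  v0 <- fba(m)$objective
  set.seed(1)
  perm <- sample.int(nrow(m$reactions))
  m2 <- m
  m2$reactions <- m$reactions[perm, ]
  rownames(m2$reactions) <- NULL
  m2$stoichiometry <- m$stoichiometry[m2$reactions$id]
  expect_equal(fba(m2)$objective, v0, tolerance = 1e-8)
})

test_that("media application closes carbon uptakes and opens the chosen source", {
  sp <- fixture_spec(seed = 6, n_linear_pathways = 3, pathway_length = 2)
  m <- make_scaffold(sp)
  cfg <- fixture_media_config(sp)
  on_m1 <- apply_media(m, "M1", cfg)
  expect_identical(
    on_m1$reactions$lower_bound[on_m1$reactions$id == "EX_X1"], -10)
  expect_identical(
    on_m1$reactions$lower_bound[on_m1$reactions$id == "EX_X2"], 0)
  expect_gt(fba(on_m1)$objective, 0)
  # base alone: no carbon, no growth
  base_only <- apply_media(m, media_condition("base_only",
    data.frame(exchange = character(0), lower = numeric(0), upper = numeric(0))),
    cfg)
  expect_equal(fba(base_only)$objective, 0, tolerance = 1e-9)
})

test_that("each carbon source feeds growth only through its own pathway", {
  sp <- fixture_spec(seed = 6, n_linear_pathways = 3, pathway_length = 2)
  m <- make_scaffold(sp)
  cfg <- fixture_media_config(sp)
  for (p in 1:3) {
    sol <- fba(apply_media(m, paste0("M", p), cfg))
    expect_gt(sol$objective, 0)
    # flux runs through the opened exchange only
    open_flux <- sol$fluxes[paste0("EX_X", p)]
    expect_lt(open_flux, 0)  # uptake
    others <- setdiff(paste0("EX_X", 1:3), paste0("EX_X", p))
    expect_true(all(abs(sol$fluxes[others]) < 1e-8))
  }
})

test_that("unknown exchange ids in media raise an error naming them", {
  m <- chain_model()
  expect_error(
    apply_media(m, media_condition("bad", data.frame(exchange = "EX_NOPE",
                                                     lower = -10, upper = 0))),
    "EX_NOPE")
})

test_that("knockouts close reactions exactly when the GPR fails", {
  m <- toy_model(list(
    EX = list(stoich = c(S_c = 1), lb = 0, ub = 10, category = "exchange"),
    R_single = list(stoich = c(S_c = -1, A_c = 1), gpr = "G1"),
    R_iso = list(stoich = c(A_c = -1, B_c = 1), gpr = "G2 or G3"),
    R_cpx = list(stoich = c(B_c = -1, C_c = 1), gpr = "G4 and G5"),
    BIOMASS = list(stoich = c(C_c = -1, BIO_c = 1), category = "enzymatic"),
    EXB = list(stoich = c(BIO_c = -1), category = "exchange")
  ), biomass = "BIOMASS")

  k1 <- knockout(m, "G1")
  expect_identical(k1$reactions$upper_bound[k1$reactions$id == "R_single"], 0)
  k2 <- knockout(m, "G2")   # isozyme partner survives
  expect_identical(k2$reactions$upper_bound[k2$reactions$id == "R_iso"], 1000)
  k3 <- knockout(m, "G4")   # complex subunit is essential
  expect_identical(k3$reactions$upper_bound[k3$reactions$id == "R_cpx"], 0)
})

test_that("knockout-disabled sets match brute-force GPR evaluation", {
  set.seed(23)
  sp <- fixture_spec(seed = 23, n_linear_pathways = 4, pathway_length = 3,
                     n_isozyme_reactions = 5, n_complex_reactions = 5)
  m <- make_scaffold(sp)
  for (rep in 1:8) {
    del <- sample(m$genes, sample(1:4, 1))
    km <- suppressMessages(knockout(m, del))
    closed <- km$reactions$id[km$reactions$upper_bound == 0 &
                                km$reactions$lower_bound == 0]
    present <- setdiff(m$genes, del)
    expected <- names(m$gpr)[!vapply(names(m$gpr), function(rid) {
      oracle_eval_gpr_string(gpr_to_string(m$gpr[[rid]]), present)
    }, logical(1))]
    expect_setequal(closed, expected)
  }
})

test_that("knockout of nothing is the identity and knockout is monotone", {
  sp <- fixture_spec(seed = 8, n_linear_pathways = 3, pathway_length = 2)
  m <- make_scaffold(sp)
  expect_identical(knockout(m, character(0)), m)
  closed_set <- function(mm) {
    mm$reactions$id[mm$reactions$upper_bound == 0 & mm$reactions$lower_bound == 0]
  }
  g <- m$genes
  small <- closed_set(suppressMessages(knockout(m, g[1])))
  large <- closed_set(suppressMessages(knockout(m, g[1:4])))
  expect_true(all(small %in% large))
})

test_that("growth binarization uses a strict threshold", {
  expect_false(binarize_growth(0))
  expect_true(binarize_growth(0.2))
  expect_false(binarize_growth(1e-6))          # exactly at threshold
  expect_true(binarize_growth(0.02, threshold = 0.1, reference_rate = 0.15))
  expect_false(binarize_growth(0.01, threshold = 0.1, reference_rate = 0.15))
  expect_error(binarize_growth(-1), "rate")
})

test_that("experimental OD curves are binarized against a third of the cohort mean", {
  flat <- rep(0, 5)
  growing <- rep(0.9, 5)
  expect_true(binarize_experiment(growing, list(growing, growing)))
  expect_false(binarize_experiment(flat, list(growing, growing, flat)))
  # cohort means 0.9, 0.9, 0.06: threshold (mean 0.62)/3 ~ 0.207
  weak <- rep(0.06, 4)
  cohort <- list(rep(0.9, 4), rep(0.9, 4), weak)
  expect_false(binarize_experiment(weak, cohort))
  expect_true(binarize_experiment(rep(0.9, 4), cohort))
  expect_error(binarize_experiment(growing, list()), "cohort")
})
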