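#' Specification of a synthetic fixture
#'
#' Describes a deterministic synthetic scaffold model, ortholog maps with
#' planted evolutionary events, and experiment tables, so the whole
#' projection/validation pipeline is exercisable without external data. The
#' fixtures are topological/logical — they emulate network shape, GPR
#' structure and evolutionary rewrite events, not real yeast biochemistry.
#'
#' @param seed Integer seed; identical specs produce byte-identical
#'   artifacts. One named pseudo-random stream is derived per generator
#'   stage, so adding stages never perturbs earlier outputs.
#' @param n_linear_pathways Number of linear carbon-assimilation pathways,
#'   each with its own exchange and transport into the cell.
#' @param pathway_length Enzymatic steps per pathway (>= 1).
#' @param n_compartments Total compartments (>= 2: extracellular `e`,
#'   cytosol `c`, plus optional internal organelles routed through by every
#'   second pathway, which creates transport reactions with and without gene
#'   associations).
#' @param event_mix Probabilities over the planted evolutionary events
#'   `loss`, `one_to_one`, `dup_in_scaffold`, `expansion_in_scaffold`,
#'   `dup_in_target`, `expansion_in_target`; must sum to 1. Events are
#'   sampled per reaction, restricted to the events its GPR shape admits
#'   (e.g. a duplication in the scaffold needs an isozyme pair).
#' @param family_size Target-family size for `expansion_in_target` (>= 3).
#' @param n_isozyme_reactions Chain reactions given OR associations
#'   (alternating two- and three-gene isozyme sets).
#' @param n_complex_reactions Chain reactions given two-gene AND (complex)
#'   associations.
#' @param n_experiments Rows in the generated experiment table.
#' @param fraction_observed Fraction of experiment rows carrying an
#'   observation.
#' @param noise_rate Per-method probability that an ortholog map omits a
#'   scaffold gene's mapping.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_linear_pathways = 6L, pathway_length = 4L,
                         n_compartments = 3L,
                         event_mix = c(loss = 0.10, one_to_one = 0.50,
                                       dup_in_scaffold = 0.10,
                                       expansion_in_scaffold = 0.10,
                                       dup_in_target = 0.10,
                                       expansion_in_target = 0.10),
                         family_size = 6L, n_isozyme_reactions = 4L,
                         n_complex_reactions = 4L, n_experiments = 30L,
                         fraction_observed = 0.8, noise_rate = 0) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (pathway_length < 1L) stop("degenerate spec: pathway_length must be >= 1")
  stopifnot(n_linear_pathways >= 1L, n_compartments >= 2L,
            n_isozyme_reactions >= 0L, n_complex_reactions >= 0L,
            family_size >= 3L, n_experiments >= 0L,
            fraction_observed >= 0, fraction_observed <= 1,
            noise_rate >= 0, noise_rate <= 1)
  stopifnot(setequal(names(event_mix),
                     c("loss", "one_to_one", "dup_in_scaffold",
                       "expansion_in_scaffold", "dup_in_target",
                       "expansion_in_target")),
            abs(sum(event_mix) - 1) < 1e-8, all(event_mix >= 0))
  structure(list(seed = as.integer(seed),
                 n_linear_pathways = as.integer(n_linear_pathways),
                 pathway_length = as.integer(pathway_length),
                 n_compartments = as.integer(n_compartments),
                 event_mix = event_mix, family_size = as.integer(family_size),
                 n_isozyme_reactions = as.integer(n_isozyme_reactions),
                 n_complex_reactions = as.integer(n_complex_reactions),
                 n_experiments = as.integer(n_experiments),
                 fraction_observed = fraction_observed,
                 noise_rate = noise_rate),
            class = "fixture_spec")
}

# one independent RNG stream per generator stage
with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  set.seed((abs(seed) * 1009L + h * 7919L) %% 2147483L + 7L)
  force(code)
}

#' Generate a synthetic scaffold model
#'
#' Builds a functional compartmentalized model: `n_linear_pathways` carbon
#' sources, each with an exchange reaction, a spontaneous transport into the
#' cytosol and a linear enzymatic chain ending in a common biomass precursor
#' pool; every second pathway is routed through an internal compartment via
#' one gene-associated and one spontaneous transport. Four gene-associated
#' reactions derive the DNA precursors (dATP, dCTP, dGTP, dTTP) from the
#' pool, and the biomass reaction consumes the pool and the precursors
#' (scaffold GC content 0.38). Designated chain reactions carry isozyme (OR)
#' or complex (AND) associations. All exchanges are open (uptake bound 10
#' mmol/gDW/h) so the raw scaffold predicts growth; media application closes
#' them.
#'
#' @param spec A [fixture_spec()].
#' @return A [metabolic_model] whose genes follow the `SC_G####` pattern.
#' @export
make_scaffold <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  P <- spec$n_linear_pathways
  L <- spec$pathway_length
  extra <- if (spec$n_compartments > 2L) {
    paste0("x", seq_len(spec$n_compartments - 2L))
  } else {
    character(0)
  }
  compartments <- data.frame(
    id = c("e", "c", extra),
    name = c("extracellular", "cytosol",
             if (length(extra)) paste("organelle", seq_along(extra)) else character(0)),
    stringsAsFactors = FALSE
  )

  gene_n <- 0L
  new_gene <- function() {
    gene_n <<- gene_n + 1L
    sprintf("SC_G%04d", gene_n)
  }

  mets <- list()
  add_met <- function(id, comp) {
    if (is.null(mets[[id]])) mets[[id]] <<- comp
    id
  }
  rxns <- list()
  add_rxn <- function(id, stoich, lb, ub, category, gpr = NULL, name = id) {
    rxns[[id]] <<- list(id = id, name = name, stoich = stoich, lb = lb,
                        ub = ub, category = category, gpr = gpr)
  }

  # which chain steps get isozyme / complex associations (deterministic draw)
  n_steps <- P * L
  shapes <- with_stage_seed(spec$seed, "scaffold", {
    sh <- rep("single", n_steps)
    k <- min(spec$n_isozyme_reactions + spec$n_complex_reactions, n_steps)
    pick <- sample(n_steps, k)
    n_iso <- min(spec$n_isozyme_reactions, k)
    if (n_iso > 0L) {
      iso <- pick[seq_len(n_iso)]
      sh[iso] <- rep(c("or2", "or3"), length.out = n_iso)
    }
    if (k > n_iso) sh[pick[(n_iso + 1L):k]] <- "and2"
    sh
  })

  gpr_for <- function(shape) {
    switch(shape,
      single = gpr_leaf(new_gene()),
      or2 = gpr_or(gpr_leaf(new_gene()), gpr_leaf(new_gene())),
      or3 = gpr_or(gpr_leaf(new_gene()), gpr_leaf(new_gene()), gpr_leaf(new_gene())),
      and2 = gpr_and(gpr_leaf(new_gene()), gpr_leaf(new_gene()))
    )
  }

  add_met("PREC_c", "c")
  step_i <- 0L
  for (p in seq_len(P)) {
    xcomp <- if (length(extra) && p %% 2L == 0L) extra[(p / 2L - 1L) %% length(extra) + 1L] else NULL
    ext <- add_met(sprintf("X%d_e", p), "e")
    cyt <- add_met(sprintf("X%d_c", p), "c")
    add_rxn(sprintf("EX_X%d", p), stats::setNames(-1, ext),
            lb = -10, ub = 1000, category = "exchange")
    add_rxn(sprintf("TR_X%d", p), stats::setNames(c(-1, 1), c(ext, cyt)),
            lb = 0, ub = 1000, category = "transport")
    work <- "c"
    cur <- cyt
    if (!is.null(xcomp)) {
      org <- add_met(sprintf("X%d_%s", p, xcomp), xcomp)
      add_rxn(sprintf("TI_X%d", p), stats::setNames(c(-1, 1), c(cur, org)),
              lb = 0, ub = 1000, category = "transport",
              gpr = gpr_leaf(new_gene()))
      work <- xcomp
      cur <- org
    }
    for (s in seq_len(L)) {
      step_i <- step_i + 1L
      prod <- if (s == L) add_met(paste0("PREC_", work), work)
              else add_met(sprintf("M%d_%d_%s", p, s, work), work)
      add_rxn(sprintf("R_%d_%d", p, s), stats::setNames(c(-1, 1), c(cur, prod)),
              lb = 0, ub = 1000, category = "enzymatic",
              gpr = gpr_for(shapes[step_i]))
      cur <- prod
    }
    if (!is.null(xcomp)) {
      add_rxn(sprintf("TB_X%d", p),
              stats::setNames(c(-1, 1), c(paste0("PREC_", work), "PREC_c")),
              lb = 0, ub = 1000, category = "transport")
    }
  }

  dntp <- c("dATP_c", "dCTP_c", "dGTP_c", "dTTP_c")
  for (d in dntp) {
    add_met(d, "c")
    add_rxn(paste0("DNTP_", sub("_c$", "", d)),
            stats::setNames(c(-1, 1), c("PREC_c", d)),
            lb = 0, ub = 1000, category = "enzymatic",
            gpr = gpr_leaf(new_gene()))
  }
  add_met("BIO_c", "c")
  # scaffold GC content 0.38: dGTP = dCTP = 0.19, dATP = dTTP = 0.31 (sum 1)
  add_rxn("BIOMASS",
          stats::setNames(c(-1, -0.31, -0.19, -0.19, -0.31, 1),
                          c("PREC_c", dntp, "BIO_c")),
          lb = 0, ub = 1000, category = "enzymatic", name = "biomass")
  add_rxn("EX_BIO", stats::setNames(-1, "BIO_c"), lb = 0, ub = 1000,
          category = "exchange")

  metabolites <- data.frame(
    id = names(mets),
    name = names(mets),
    compartment = unlist(mets, use.names = FALSE),
    boundary = FALSE,
    stringsAsFactors = FALSE
  )
  reactions <- data.frame(
    id = vapply(rxns, `[[`, character(1), "id"),
    name = vapply(rxns, `[[`, character(1), "name"),
    lower_bound = vapply(rxns, `[[`, numeric(1), "lb"),
    upper_bound = vapply(rxns, `[[`, numeric(1), "ub"),
    category = vapply(rxns, `[[`, character(1), "category"),
    stringsAsFactors = FALSE
  )
  rownames(reactions) <- NULL
  gpr <- lapply(rxns, `[[`, "gpr")
  names(gpr) <- reactions$id
  metabolic_model(
    id = sprintf("synthetic_scaffold_seed%d", spec$seed),
    compartments = compartments,
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stats::setNames(lapply(rxns, `[[`, "stoich"), reactions$id),
    gpr = gpr,
    biomass_reaction = "BIOMASS"
  )
}

#' Generate ortholog maps with planted evolutionary events
#'
#' Assigns one evolutionary event per GPR-bearing scaffold reaction, drawn
#' from the spec's `event_mix` restricted to the events the reaction's GPR
#' shape admits (a scaffold duplication needs a two-gene isozyme set, a
#' scaffold expansion a three-gene one). The four DNA-precursor reactions
#' are never assigned a loss: losing a universally essential gene yields a
#' model that can never grow, while the projection workflow targets
#' functional models, so planted losses live in dispensable routes. Each
#' method's map is a noisy view (per-method omission rate `noise_rate`) of
#' the planted truth; multi-target families carry a shared paralog-group
#' label.
#'
#' @param scaffold A [make_scaffold()] model.
#' @param spec The [fixture_spec()] used to build it.
#' @param n_methods Number of ortholog-detection methods to emulate.
#' @return List with `maps` (list of [ortholog_map]), `ground_truth`
#'   (list: `reaction_cases`, `gene_cases` — named case labels M1/M3–M7),
#'   and `truth_pairs` (the noise-free pair table). Target genes follow the
#'   `TG_G####` pattern.
#' @export
make_ortholog_maps <- function(scaffold, spec, n_methods = 3L) {
  stopifnot(inherits(scaffold, "metabolic_model"), inherits(spec, "fixture_spec"))
  tg_n <- 0L
  new_target <- function() {
    tg_n <<- tg_n + 1L
    sprintf("TG_G%04d", tg_n)
  }
  pairs <- data.frame(scaffold = character(0), target = character(0),
                      group = character(0), stringsAsFactors = FALSE)
  add_pair <- function(sg, tg, group = NA_character_) {
    pairs[nrow(pairs) + 1L, ] <<- list(sg, tg, group)
  }
  reaction_cases <- character(0)
  gene_cases <- character(0)

  with_stage_seed(spec$seed, "orthology", {
    for (rid in names(scaffold$gpr)) {
      ga <- scaffold$gpr[[rid]]
      genes <- gpr_genes(ga)
      is_or <- !is.null(ga$op) && ga$op == "or"
      eligible <- c("one_to_one", "dup_in_target", "expansion_in_target")
      if (!startsWith(rid, "DNTP_")) eligible <- c(eligible, "loss")
      if (is_or && length(genes) == 2L) eligible <- c(eligible, "dup_in_scaffold")
      if (is_or && length(genes) == 3L) eligible <- c(eligible, "expansion_in_scaffold")
      w <- spec$event_mix[eligible]
      event <- if (sum(w) > 0) sample(eligible, 1L, prob = w) else "one_to_one"

      case <- switch(event,
        loss = {
          gene_cases[genes] <- "M1"
          "M1"
        },
        one_to_one = {
          for (g in genes) add_pair(g, new_target())
          gene_cases[genes] <- "M3"
          "M3"
        },
        dup_in_scaffold = {
          tg <- new_target()
          for (g in genes) add_pair(g, tg)
          gene_cases[genes] <- "M4"
          "M4"
        },
        expansion_in_scaffold = {
          tg <- new_target()
          for (g in genes) add_pair(g, tg)
          gene_cases[genes] <- "M5"
          "M5"
        },
        dup_in_target = {
          fam <- paste0("F_", genes[1L])
          add_pair(genes[1L], new_target(), fam)
          add_pair(genes[1L], new_target(), fam)
          gene_cases[genes[1L]] <- "M6"
          for (g in genes[-1L]) {
            add_pair(g, new_target())
            gene_cases[g] <- "M3"
          }
          "M6"
        },
        expansion_in_target = {
          fam <- paste0("F_", genes[1L])
          for (k in seq_len(spec$family_size)) add_pair(genes[1L], new_target(), fam)
          gene_cases[genes[1L]] <- "M7"
          for (g in genes[-1L]) {
            add_pair(g, new_target())
            gene_cases[g] <- "M3"
          }
          "M7"
        }
      )
      reaction_cases[rid] <- case
    }
  })

  maps <- lapply(seq_len(n_methods), function(k) {
    kept <- with_stage_seed(spec$seed, paste0("map_noise_", k), {
      sgs <- unique(pairs$scaffold)
      drop <- sgs[stats::runif(length(sgs)) < spec$noise_rate]
      !(pairs$scaffold %in% drop)
    })
    ortholog_map(paste0("method", k), pairs[kept, , drop = FALSE])
  })
  list(maps = maps,
       ground_truth = list(reaction_cases = reaction_cases,
                           gene_cases = gene_cases),
       truth_pairs = pairs)
}

#' Media configuration for a fixture model
#'
#' One media preset per pathway carbon source (`M1`, `M2`, ...), each
#' opening that pathway's exchange to an uptake of 10 mmol/gDW/h on top of
#' an empty base (the toy network needs no non-carbon nutrients).
#'
#' @param spec A [fixture_spec()].
#' @return A [media_config].
#' @export
fixture_media_config <- function(spec) {
  media <- lapply(seq_len(spec$n_linear_pathways), function(p) {
    media_condition(paste0("M", p),
                    data.frame(exchange = sprintf("EX_X%d", p),
                               lower = -10, upper = 1000,
                               stringsAsFactors = FALSE))
  })
  names(media) <- paste0("M", seq_len(spec$n_linear_pathways))
  media_config(base = data.frame(exchange = character(0), lower = numeric(0),
                                 upper = numeric(0)),
               media = media)
}

#' Generate an experiment table from a target model
#'
#' Enumerates (media x knockout) combinations — wild type plus every
#' single-gene deletion on each media preset — and computes each row's
#' ground-truth growth by simulation on the uncorrupted target model. A
#' chosen number of growth and no-growth rows receive observations; planted
#' disagreements are then created by flipping `flip_fp` observations of
#' predicted-growth rows to "no growth" (false positives) and `flip_fn`
#' observations of predicted-no-growth rows to "growth" (false negatives).
#' Remaining rows are kept without observation, up to `n_experiments` rows.
#'
#' @param target A functional [metabolic_model].
#' @param spec The [fixture_spec()].
#' @param config A [media_config] (defaults to [fixture_media_config()]).
#' @param observed_growth,observed_nogrowth Numbers of rows of each
#'   simulated class to observe; `NULL` derives them from
#'   `spec$fraction_observed` and class availability.
#' @param flip_fp,flip_fn Planted false positives / false negatives.
#' @param threshold Growth threshold for the ground-truth binarization.
#' @return Experiment `data.frame` (`id`, `media`, `ko_genes`, `observed`,
#'   `source`) with the simulated ground truth attached as the
#'   `ground_truth` attribute.
#' @export
make_experiments <- function(target, spec, config = fixture_media_config(spec),
                             observed_growth = NULL, observed_nogrowth = NULL,
                             flip_fp = 0L, flip_fn = 0L, threshold = 1e-6) {
  validate_metabolic_model(target)
  grid <- do.call(rbind, lapply(names(config$media), function(mn) {
    data.frame(media = mn, ko = c("", target$genes), stringsAsFactors = FALSE)
  }))
  sim <- logical(nrow(grid))
  for (mn in unique(grid$media)) {
    base <- apply_media(target, mn, config)
    for (i in which(grid$media == mn)) {
      m <- if (nzchar(grid$ko[i])) suppressMessages(knockout(base, grid$ko[i])) else base
      sol <- fba(m)
      rate <- if (sol$status == "optimal") sol$objective else 0
      sim[i] <- binarize_growth(rate, threshold)
    }
  }

  with_stage_seed(spec$seed, "experiments", {
    ord <- sample.int(nrow(grid))
    grid <- grid[ord, , drop = FALSE]
    sim <- sim[ord]
    if (is.null(observed_growth) || is.null(observed_nogrowth)) {
      n_obs <- round(min(spec$n_experiments, nrow(grid)) * spec$fraction_observed)
      avail_t <- sum(sim)
      observed_growth <- min(round(n_obs * avail_t / length(sim)), avail_t)
      observed_nogrowth <- min(n_obs - observed_growth, sum(!sim))
    }
    if (observed_growth > sum(sim)) {
      stop("fixture cannot supply ", observed_growth,
           " growth observations (only ", sum(sim), " growing combinations)")
    }
    if (observed_nogrowth > sum(!sim)) {
      stop("fixture cannot supply ", observed_nogrowth,
           " no-growth observations (only ", sum(!sim),
           " non-growing combinations)")
    }
    pool_t <- which(sim)
    pool_f <- which(!sim)
    idx_t <- pool_t[sample.int(length(pool_t), observed_growth)]
    idx_f <- pool_f[sample.int(length(pool_f), observed_nogrowth)]
    observed <- rep(NA, nrow(grid))
    observed[idx_t] <- TRUE
    observed[idx_f] <- FALSE
    stopifnot(flip_fp <= observed_growth, flip_fn <= observed_nogrowth)
    observed[idx_t[sample.int(length(idx_t), flip_fp)]] <- FALSE  # -> false positives
    observed[idx_f[sample.int(length(idx_f), flip_fn)]] <- TRUE   # -> false negatives

    keep <- unique(c(idx_t, idx_f,
                     setdiff(seq_len(nrow(grid)), c(idx_t, idx_f))))
    keep <- keep[seq_len(min(spec$n_experiments, nrow(grid)))]
    keep <- sort(keep)
    out <- data.frame(
      id = sprintf("E%04d", seq_along(keep)),
      media = grid$media[keep],
      ko_genes = grid$ko[keep],
      observed = observed[keep],
      source = "synthetic",
      stringsAsFactors = FALSE
    )
    attr(out, "ground_truth") <- sim[keep]
    out
  })
}
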