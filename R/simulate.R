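#' Media conditions
#'
#' A media condition is a set of exchange-reaction bounds (mmol/gDW/h)
#' layered on top of a base condition in which every carbon uptake is closed
#' and only base (non-carbon) nutrients are available.
#'
#' @param name Media name token (e.g. `"YNBD"`).
#' @param exchange_bounds `data.frame` with columns `exchange`, `lower`,
#'   `upper`.
#' @return An object of class `media_condition`.
#' @export
media_condition <- function(name, exchange_bounds) {
  exchange_bounds <- as.data.frame(exchange_bounds, stringsAsFactors = FALSE)
  stopifnot(all(c("exchange", "lower", "upper") %in% names(exchange_bounds)),
            all(exchange_bounds$lower <= exchange_bounds$upper))
  structure(list(name = name, exchange_bounds = exchange_bounds),
            class = "media_condition")
}

#' Load a media configuration from TSV
#'
#' Expects columns `media`, `exchange`, `lower`, `upper`. Rows with
#' `media == "base"` define the base (non-carbon) nutrient exchanges opened
#' in every condition; all other media names become named presets layered on
#' top of the base.
#'
#' @param path Path to the TSV file.
#' @return An object of class `media_config`: list with `base` (a
#'   `data.frame` of base exchange bounds) and `media` (named list of
#'   [media_condition] objects).
#' @export
load_media_config <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("media", "exchange", "lower", "upper") %in% names(df)))
  media_config(base = df[df$media == "base", c("exchange", "lower", "upper")],
               media = lapply(split(df[df$media != "base", ], df$media[df$media != "base"]),
                              function(d) media_condition(d$media[1L],
                                d[, c("exchange", "lower", "upper")])))
}

#' @rdname load_media_config
#' @param base `data.frame` of base exchange bounds (`exchange`, `lower`,
#'   `upper`).
#' @param media Named list of [media_condition] objects.
#' @export
media_config <- function(base, media) {
  base <- as.data.frame(base, stringsAsFactors = FALSE)
  structure(list(base = base, media = media), class = "media_config")
}

#' Write a media configuration to TSV
#'
#' @param config A [media_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_media_config <- function(config, path) {
  rows <- rbind(
    if (nrow(config$base)) cbind(media = "base", config$base),
    do.call(rbind, lapply(config$media, function(mc) {
      cbind(media = mc$name, mc$exchange_bounds)
    }))
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a media condition to a model
#'
#' Sets every exchange reaction's lower bound to 0 (no uptake), then opens
#' the base non-carbon nutrients, then applies the media's own exchange
#' bounds last. Uptake is a negative exchange flux, so "opening" an exchange
#' means lowering its lower bound.
#'
#' @param model A [metabolic_model].
#' @param media A [media_condition], or the name of a preset in `config`.
#' @param config Optional [media_config] providing the base exchanges (and
#'   presets when `media` is a name).
#' @param base_uptake Default uptake bound for base nutrients when `config`
#'   carries no explicit bound, mmol/gDW/h.
#' @return The constrained model.
#' @export
apply_media <- function(model, media, config = NULL, base_uptake = 10) {
  validate_metabolic_model(model)
  if (is.character(media)) {
    if (is.null(config) || is.null(config$media[[media]])) {
      stop("unknown media preset: ", media)
    }
    media <- config$media[[media]]
  }
  stopifnot(inherits(media, "media_condition"))
  is_ex <- model$reactions$category == "exchange"
  model$reactions$lower_bound[is_ex] <- pmax(model$reactions$lower_bound[is_ex], 0)
  if (!is.null(config) && nrow(config$base)) {
    for (i in seq_len(nrow(config$base))) {
      j <- match(config$base$exchange[i], model$reactions$id)
      if (is.na(j)) stop("unknown exchange reaction in base media: ",
                         config$base$exchange[i])
      model$reactions$lower_bound[j] <- config$base$lower[i]
      model$reactions$upper_bound[j] <- config$base$upper[i]
    }
  }
  eb <- media$exchange_bounds
  for (i in seq_len(nrow(eb))) {
    j <- match(eb$exchange[i], model$reactions$id)
    if (is.na(j)) stop("unknown exchange reaction in media ", media$name,
                       ": ", eb$exchange[i])
    model$reactions$lower_bound[j] <- eb$lower[i]
    model$reactions$upper_bound[j] <- eb$upper[i]
  }
  model
}

#' Propagate gene knockouts through GPRs
#'
#' Every reaction whose gene association evaluates to false once the deleted
#' genes are removed has its bounds set to (0, 0); reactions without a gene
#' association are untouched. Unknown gene ids are allowed and logged with a
#' message.
#'
#' @param model A [metabolic_model].
#' @param deleted_genes Character vector of genes to delete.
#' @return The constrained model.
#' @export
knockout <- function(model, deleted_genes) {
  unknown <- setdiff(deleted_genes, model$genes)
  if (length(unknown)) {
    message("knockout: gene id(s) not in model: ", paste(unknown, collapse = ", "))
  }
  present <- setdiff(model$genes, deleted_genes)
  for (rid in names(model$gpr)) {
    if (!evaluate_gpr(model$gpr[[rid]], present)) {
      j <- match(rid, model$reactions$id)
      model$reactions$lower_bound[j] <- 0
      model$reactions$upper_bound[j] <- 0
    }
  }
  model
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction's flux subject to steady-state mass
#' balance (S v = 0 over non-boundary metabolites) and the flux bounds, by
#' the simplex method. Every optimal solution is checked to satisfy mass
#' balance and bounds within 1e-6.
#'
#' @param model A [metabolic_model].
#' @param objective Reaction id to maximize; defaults to the biomass
#'   reaction.
#' @return An object of class `flux_solution`: list with `status`
#'   (`"optimal"` or `"infeasible"`; all fluxes are bounded, so the LP is
#'   never unbounded), `objective` (growth rate, 1/h, `NA` if not optimal)
#'   and `fluxes` (named numeric vector).
#' @export
fba <- function(model, objective = model$biomass_reaction) {
  validate_metabolic_model(model)
  if (is.na(objective) || !(objective %in% model$reactions$id)) {
    stop("objective reaction not found: ", objective)
  }
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  a <- as.numeric(model$reactions$id == objective)
  sol <- solve_lp(a, S, lb, ub, maximize = TRUE)
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, objective = NA_real_,
                          fluxes = stats::setNames(rep(NA_real_, length(lb)),
                                                   model$reactions$id)),
                     class = "flux_solution"))
  }
  v <- stats::setNames(sol$x, model$reactions$id)
  resid <- max(abs(S %*% v))
  if (resid > 1e-6) stop("FBA solution violates mass balance (residual ", resid, ")")
  if (any(v < lb - 1e-6) || any(v > ub + 1e-6)) {
    stop("FBA solution violates flux bounds")
  }
  structure(list(status = "optimal", objective = unname(v[objective]),
                 fluxes = v),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> ", x$status, ", objective = ",
      format(x$objective), "\n", sep = "")
  invisible(x)
}

# steady-state FBA problem: maximize a'v, S v = 0, lb <= v <= ub
solve_lp <- function(a, S, lb, ub, maximize = TRUE) {
  res <- lp_bounded(a, S, rep(0, nrow(S)), lb, ub, maximize = maximize)
  list(status = res$status, x = res$x)
}

#' Binarize a simulated growth rate
#'
#' @param rate Predicted growth rate (1/h); must be at least -1e-6.
#' @param threshold Absolute growth threshold (1/h), default 1e-6; growth is
#'   declared iff `rate > threshold` (strict).
#' @param reference_rate Optional wild-type rate on a reference medium; when
#'   given, `threshold` is interpreted as a fraction of it.
#' @return Logical scalar.
#' @export
binarize_growth <- function(rate, threshold = 1e-6, reference_rate = NULL) {
  stopifnot(rate >= -1e-6)
  if (!is.null(reference_rate)) threshold <- threshold * reference_rate
  rate > threshold
}

#' Binarize an experimental OD growth curve
#'
#' A culture is scored as growing iff the mean OD of its curve exceeds one
#' third of the mean OD across all curves of its cohort.
#'
#' @param od_curve Numeric vector of OD readings over time.
#' @param cohort_curves Non-empty list of OD vectors (the cohort of mutants
#'   measured together; may include `od_curve` itself).
#' @return Logical scalar.
#' @export
binarize_experiment <- function(od_curve, cohort_curves) {
  stopifnot(length(od_curve) > 0)
  if (length(cohort_curves) == 0L) stop("empty cohort")
  cohort_mean <- mean(vapply(cohort_curves, mean, numeric(1)))
  mean(od_curve) > cohort_mean / 3
}

#' Flux variability analysis
#'
#' Computes the attainable flux range of each requested reaction under the
#' model's current bounds.
#'
#' @param model A [metabolic_model].
#' @param reactions Reaction ids; default all.
#' @return `data.frame` with columns `reaction`, `min`, `max`; all-`NA`
#'   ranges when the base LP is infeasible.
#' @export
flux_variability <- function(model, reactions = model$reactions$id) {
  validate_metabolic_model(model)
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    a <- as.numeric(model$reactions$id == reactions[i])
    hi <- solve_lp(a, S, lb, ub, maximize = TRUE)
    lo <- solve_lp(a, S, lb, ub, maximize = FALSE)
    if (hi$status == "optimal") out$max[i] <- sum(a * hi$x)
    if (lo$status == "optimal") out$min[i] <- sum(a * lo$x)
  }
  out
}
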