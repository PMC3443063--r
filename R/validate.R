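#' Read an experiment table
#'
#' TSV with columns `id`, `media`, `ko_genes` (semicolon-separated, empty
#' for wild type), `observed` (`yes` / `no` / empty when the experiment has
#' no usable observation) and `source` (citation text).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with `observed` as logical (`NA` when unpaired).
#' @export
read_experiment_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("id", "media", "ko_genes", "observed") %in% names(df)))
  if (is.null(df$source)) df$source <- ""
  obs <- tolower(trimws(df$observed))
  df$observed <- ifelse(obs == "yes", TRUE, ifelse(obs == "no", FALSE, NA))
  df
}

#' Write an experiment table
#'
#' @param experiments Experiment `data.frame` (see [read_experiment_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_table <- function(experiments, path) {
  df <- experiments
  df$observed <- ifelse(is.na(df$observed), "",
                        ifelse(df$observed, "yes", "no"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run growth experiments through simulation
#'
#' For each experiment: apply the media condition, propagate the gene
#' knockouts, run FBA and binarize the predicted growth rate. Experiments
#' whose media cannot be resolved are marked errored and excluded from
#' scoring; experiments without an observation are simulated but carry
#' `observed = NA`.
#'
#' @param model A functional [metabolic_model].
#' @param experiments Experiment `data.frame` (columns `id`, `media`,
#'   `ko_genes`, `observed`; see [read_experiment_table()]).
#' @param config A [media_config] resolving the media names.
#' @param threshold Growth threshold passed to [binarize_growth()].
#' @return The experiment `data.frame` with added columns `growth_rate`,
#'   `predicted` (logical) and `errored`.
#' @export
run_experiments <- function(model, experiments, config, threshold = 1e-6) {
  validate_metabolic_model(model)
  experiments$growth_rate <- NA_real_
  experiments$predicted <- NA
  experiments$errored <- FALSE
  for (i in seq_len(nrow(experiments))) {
    m <- tryCatch(apply_media(model, experiments$media[i], config),
                  error = function(e) {
                    message("experiment ", experiments$id[i], " errored: ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(m)) {
      experiments$errored[i] <- TRUE
      next
    }
    kos <- experiments$ko_genes[i]
    genes <- if (is.na(kos) || !nzchar(kos)) character(0) else
      trimws(strsplit(kos, ";", fixed = TRUE)[[1L]])
    m <- suppressMessages(knockout(m, genes))
    sol <- fba(m)
    rate <- if (sol$status == "optimal") sol$objective else 0
    experiments$growth_rate[i] <- rate
    experiments$predicted[i] <- binarize_growth(rate, threshold)
  }
  experiments
}

#' Confusion matrix with geometric-mean accuracy
#'
#' The positive class is observed growth. Derived metrics: sensitivity
#' `tp/(tp+fn)`, specificity `tn/(tn+fp)` and their geometric mean. When a
#' class is absent (zero denominator), the undefined metric is `NA` and the
#' geometric mean falls back to the defined one, with `gmean_defined`
#' flagging the degeneracy.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return An object of class `confusion_matrix` with fields `tp`, `tn`,
#'   `fp`, `fn`, `sensitivity`, `specificity`, `gmean_accuracy`,
#'   `exact_agreements`, `total`, `gmean_defined`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  defined <- !is.na(sens) && !is.na(spec)
  gmean <- if (defined) {
    sqrt(sens * spec)
  } else if (!is.na(sens)) {
    sens
  } else if (!is.na(spec)) {
    spec
  } else {
    NA_real_
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec,
                 gmean_accuracy = gmean, exact_agreements = tp + tn,
                 total = tp + tn + fp + fn, gmean_defined = defined),
            class = "confusion_matrix")
}

#' Score observed vs predicted growth
#'
#' @param pairs `data.frame` with logical columns `observed` and `predicted`
#'   (e.g. from [run_experiments()]); rows with `NA` observation or marked
#'   errored are excluded from scoring.
#' @return A [confusion_matrix()].
#' @export
score <- function(pairs) {
  stopifnot(all(c("observed", "predicted") %in% names(pairs)))
  if (!is.null(pairs$errored)) pairs <- pairs[!pairs$errored, , drop = FALSE]
  pairs <- pairs[!is.na(pairs$observed) & !is.na(pairs$predicted), ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) stop("no scored pairs: every row lacks an observation")
  confusion_matrix(
    tp = sum(pairs$observed & pairs$predicted),
    tn = sum(!pairs$observed & !pairs$predicted),
    fp = sum(!pairs$observed & pairs$predicted),
    fn = sum(pairs$observed & !pairs$predicted)
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> n = ", x$total,
      " (TP ", x$tp, ", TN ", x$tn, ", FP ", x$fp, ", FN ", x$fn, ")\n",
      "  sensitivity: ", format_metric(x$sensitivity), "\n",
      "  specificity: ", format_metric(x$specificity), "\n",
      "  geometric-mean accuracy: ", format_metric(x$gmean_accuracy),
      if (!x$gmean_defined) " (one class absent)" else "", "\n", sep = "")
  invisible(x)
}

format_metric <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)

#' Write a validation report
#'
#' Produces a per-experiment verdict table (TSV) — listing false positives
#' and false negatives so they can target improvements in gene annotation —
#' and a machine-readable JSON summary that round-trips the confusion
#' matrix at full precision.
#'
#' @param cm A [confusion_matrix()].
#' @param results Result `data.frame` from [run_experiments()].
#' @param tsv,json Output paths (`NULL` to skip either).
#' @return `cm`, invisibly.
#' @export
write_validation_report <- function(cm, results, tsv = NULL, json = NULL) {
  verdict <- ifelse(results$errored %||% FALSE, "errored",
             ifelse(is.na(results$observed), "unpaired",
             ifelse(results$observed & results$predicted, "TP",
             ifelse(!results$observed & !results$predicted, "TN",
             ifelse(results$predicted, "FP", "FN")))))
  df <- cbind(results, verdict = verdict)
  df$observed <- ifelse(is.na(df$observed), "",
                        ifelse(df$observed, "yes", "no"))
  if (!is.null(tsv)) {
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(confusion = unclass(cm),
           false_positives = results$id[verdict == "FP"],
           false_negatives = results$id[verdict == "FN"]),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(cm)
}

#' Read a validation report JSON back into a confusion matrix
#'
#' @param path Path to a JSON written by [write_validation_report()].
#' @return A [confusion_matrix()].
#' @export
read_validation_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  confusion_matrix(tp = j$confusion$tp, tn = j$confusion$tn,
                   fp = j$confusion$fp, fn = j$confusion$fn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
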