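#' Load an ortholog map from delimited text
#'
#' Expects two or three tab-separated columns: scaffold gene id, target gene
#' id, and an optional paralog-group label. A header line whose first field
#' is `scaffold` (case-insensitive) is skipped. Duplicate rows are collapsed.
#'
#' @param path Path to the TSV file.
#' @param method_name Token naming the ortholog-detection method the map
#'   comes from (used in consensus voting).
#' @return An object of class `ortholog_map`: list with `method` and `pairs`
#'   (`data.frame` with columns `scaffold`, `target`, `group`; `group` is
#'   `NA` where no label was given).
#' @export
load_ortholog_map <- function(path, method_name) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines_kept <- which(nzchar(trimws(lines)))
  rows <- strsplit(lines[lines_kept], "\t", fixed = TRUE)
  if (length(rows) && grepl("^scaffold$", trimws(rows[[1L]][1L]), ignore.case = TRUE)) {
    rows <- rows[-1L]
    lines_kept <- lines_kept[-1L]
  }
  out <- data.frame(scaffold = character(0), target = character(0),
                    group = character(0), stringsAsFactors = FALSE)
  for (j in seq_along(rows)) {
    f <- trimws(rows[[j]])
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
      stop("ortholog map format error in ", path, " at line ", lines_kept[j],
           ": need at least two non-empty columns (scaffold, target)")
    }
    out[nrow(out) + 1L, ] <- list(f[1L], f[2L],
                                  if (length(f) >= 3L && nzchar(f[3L])) f[3L] else NA_character_)
  }
  out <- unique(out)
  rownames(out) <- NULL
  ortholog_map(method_name, out)
}

#' @rdname load_ortholog_map
#' @param pairs A `data.frame` with columns `scaffold`, `target` and
#'   optionally `group`.
#' @export
ortholog_map <- function(method_name, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (is.null(pairs$group)) pairs$group <- NA_character_
  stopifnot(all(c("scaffold", "target") %in% names(pairs)),
            all(nzchar(pairs$scaffold)), all(nzchar(pairs$target)))
  structure(list(method = method_name,
                 pairs = unique(pairs[, c("scaffold", "target", "group")])),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("<ortholog_map> ", x$method, ": ", nrow(x$pairs), " pairs, ",
      length(unique(x$pairs$scaffold)), " scaffold genes\n", sep = "")
  invisible(x)
}

#' Build a consensus homolog map by voting
#'
#' For every scaffold gene, candidate target paralog groups are assembled
#' from all input maps: within one method, rows sharing a group label form a
#' group (unlabelled rows are singleton groups); across methods, groups that
#' share any target gene are merged (connected components of the support
#' graph). Each merged group receives one vote per method that supports it.
#' Groups below `min_votes` are dropped; with `consensus = "top"` (divergent
#' prediction mode) only the group(s) with the maximal vote count are kept,
#' ties being retained together and logged.
#'
#' @param maps List of [ortholog_map] objects (at least one).
#' @param min_votes Minimum votes for a group to be retained (default 1).
#' @param consensus `"top"` (default) keeps only the top-voted group(s) per
#'   scaffold gene; `"all"` keeps every group passing `min_votes`.
#' @return An object of class `consensus_map`: named list, scaffold gene id
#'   to a list of groups, each `list(genes = <character>, votes = <int>)`.
#'   Attributes: `n_methods`, `ties` (scaffold genes with tied top groups).
#' @export
build_consensus <- function(maps, min_votes = 1L, consensus = c("top", "all")) {
  consensus <- match.arg(consensus)
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "ortholog_map")))
  methods <- vapply(maps, function(m) m$method, character(1))
  if (anyDuplicated(methods)) stop("duplicate method names in input maps")

  all_pairs <- do.call(rbind, lapply(maps, function(m) {
    if (nrow(m$pairs) == 0L) return(NULL)
    cbind(m$pairs, method = m$method, stringsAsFactors = FALSE)
  }))
  out <- list()
  ties <- character(0)
  if (!is.null(all_pairs)) {
    for (sg in sort(unique(all_pairs$scaffold))) {
      rows <- all_pairs[all_pairs$scaffold == sg, , drop = FALSE]
      # per-method groups: shared label, else singleton per target
      units <- list()  # each: list(targets, method)
      for (meth in unique(rows$method)) {
        mr <- rows[rows$method == meth, , drop = FALSE]
        lab <- ifelse(is.na(mr$group), paste0("\x1f", mr$target), mr$group)
        for (l in unique(lab)) {
          units[[length(units) + 1L]] <-
            list(targets = sort(unique(mr$target[lab == l])), method = meth)
        }
      }
      comp <- merge_overlapping(lapply(units, `[[`, "targets"))
      groups <- lapply(sort(unique(comp)), function(ci) {
        in_ci <- comp == ci
        list(genes = sort(unique(unlist(lapply(units[in_ci], `[[`, "targets")))),
             votes = length(unique(vapply(units[in_ci], `[[`, character(1), "method"))))
      })
      groups <- groups[vapply(groups, `[[`, integer(1), "votes") >= min_votes]
      if (length(groups) == 0L) next
      if (consensus == "top") {
        v <- vapply(groups, `[[`, integer(1), "votes")
        groups <- groups[v == max(v)]
        if (length(groups) > 1L) ties <- c(ties, sg)
      }
      # canonical order: votes desc, then first gene
      key <- vapply(groups, function(g) g$genes[[1L]], character(1))
      v <- vapply(groups, `[[`, integer(1), "votes")
      out[[sg]] <- groups[order(-v, key)]
    }
  }
  structure(out, class = "consensus_map", n_methods = length(maps), ties = ties)
}

# connected components over sets that share elements; returns component index
merge_overlapping <- function(sets) {
  n <- length(sets)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a < b && length(intersect(sets[[a]], sets[[b]])) > 0L) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Union of retained target genes for a scaffold gene
#'
#' @param map A [build_consensus()] result.
#' @param gene Scaffold gene id.
#' @return Character vector of target genes (empty when unmapped).
#' @export
consensus_targets <- function(map, gene) {
  entry <- map[[gene]]
  if (is.null(entry)) return(character(0))
  sort(unique(unlist(lapply(entry, `[[`, "genes"))))
}

#' @export
print.consensus_map <- function(x, ...) {
  cat("<consensus_map> ", length(x), " scaffold genes, ",
      attr(x, "n_methods"), " methods", sep = "")
  if (length(attr(x, "ties"))) cat(" (", length(attr(x, "ties")), " ties)", sep = "")
  cat("\n")
  invisible(x)
}

#' Serialize a consensus map to TSV
#'
#' Columns: scaffold gene, comma-separated target genes of the group, votes.
#'
#' @param map A [build_consensus()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(map, path) {
  rows <- do.call(rbind, lapply(names(map), function(sg) {
    do.call(rbind, lapply(map[[sg]], function(g) {
      data.frame(scaffold = sg, targets = paste(g$genes, collapse = ","),
                 votes = g$votes, stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(rows)) {
    rows <- data.frame(scaffold = character(0), targets = character(0),
                       votes = integer(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
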