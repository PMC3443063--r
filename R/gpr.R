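#' Gene-Protein-Reaction (GPR) association trees
#'
#' A GPR association is a boolean formula over gene identifiers that states
#' which combinations of gene products make a reaction available: `and` joins
#' subunits of a complex (all required), `or` joins isozymes (any suffices).
#' Trees are built from [gpr_leaf()], [gpr_and()] and [gpr_or()], or parsed
#' from the COBRA notes dialect with [parse_gpr()].
#'
#' @name gpr
NULL

#' Construct GPR tree nodes
#'
#' @param gene A single non-empty gene identifier.
#' @param ... Child nodes (GPR trees), at least one.
#' @return An object of class `gpr`, a tree whose nodes are lists with an
#'   `op` field (`"leaf"`, `"and"` or `"or"`), a `gene` field on leaves and a
#'   `children` list on internal nodes.
#' @examples
#' gpr_or(gpr_leaf("YGR032W"), gpr_leaf("YLR342W"))
#' @export
gpr_leaf <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  structure(list(op = "leaf", gene = gene), class = "gpr")
}

#' @rdname gpr_leaf
#' @export
gpr_and <- function(...) new_gpr_node("and", list(...))

#' @rdname gpr_leaf
#' @export
gpr_or <- function(...) new_gpr_node("or", list(...))

new_gpr_node <- function(op, children) {
  if (length(children) == 0L) stop("empty '", op, "' node is not allowed")
  stopifnot(all(vapply(children, inherits, logical(1), "gpr")))
  if (length(children) == 1L) return(children[[1L]])
  structure(list(op = op, children = children), class = "gpr")
}

is_gpr <- function(x) inherits(x, "gpr")

#' Parse a GPR string
#'
#' Parses the COBRA notes dialect: gene identifiers, parentheses and the
#' case-insensitive operators `and` / `or` (`and` binds tighter than `or`).
#'
#' @param text A single GPR string, e.g. `"(YGR032W or YLR342W)"`.
#' @return A [gpr] tree, or `NULL` for an empty/whitespace-only string.
#' @examples
#' parse_gpr("A and (B or C)")
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)

  # tokenize: identifiers (anything but whitespace/parens), parens
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  tokens <- regmatches(text, list(m))[[1L]]
  pos <- as.integer(m)
  i <- 0L

  peek <- function() if (i < length(tokens)) tokens[[i + 1L]] else NULL
  advance <- function() {
    i <<- i + 1L
    tokens[[i]]
  }
  err <- function(msg, at = if (i < length(tokens)) pos[[i + 1L]] else nchar(text) + 1L) {
    stop("GPR parse error at position ", at, ": ", msg, " in ", sQuote(text), call. = FALSE)
  }
  is_op <- function(tok, what) !is.null(tok) && tolower(tok) == what

  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) err("unexpected end of input")
    if (tok == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) err("unbalanced parentheses, expected ')'")
      advance()
      return(node)
    }
    if (tok == ")") err("unexpected ')'")
    if (is_op(tok, "and") || is_op(tok, "or")) {
      err(paste0("dangling operator '", tok, "'"))
    }
    advance()
    gpr_leaf(tok)
  }
  parse_and <- function() {
    children <- list(parse_factor())
    while (is_op(peek(), "and")) {
      advance()
      children <- c(children, list(parse_factor()))
    }
    new_gpr_node("and", children)
  }
  parse_or <- function() {
    children <- list(parse_and())
    while (is_op(peek(), "or")) {
      advance()
      children <- c(children, list(parse_and()))
    }
    new_gpr_node("or", children)
  }

  node <- parse_or()
  if (!is.null(peek())) err("unexpected token ", sQuote(peek()))
  node
}

#' Format a GPR tree back to a string
#'
#' @param assoc A [gpr] tree or `NULL`.
#' @return A GPR string in the COBRA dialect (`""` for `NULL`).
#' @export
gpr_to_string <- function(assoc) {
  if (is.null(assoc)) return("")
  fmt <- function(node, parent_op) {
    if (node$op == "leaf") return(node$gene)
    sep <- if (node$op == "and") " and " else " or "
    s <- paste(vapply(node$children, fmt, character(1), parent_op = node$op),
               collapse = sep)
    # parenthesize 'or' under 'and' (and any nested group for readability)
    if (!is.null(parent_op) && parent_op == "and" && node$op == "or") {
      s <- paste0("(", s, ")")
    }
    s
  }
  fmt(assoc, NULL)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a GPR tree
#'
#' @param assoc A [gpr] tree or `NULL`.
#' @return Sorted unique character vector of gene identifiers.
#' @export
gpr_genes <- function(assoc) {
  if (is.null(assoc)) return(character(0))
  rec <- function(node) {
    if (node$op == "leaf") return(node$gene)
    unlist(lapply(node$children, rec))
  }
  sort(unique(rec(assoc)))
}

#' Evaluate a GPR under a gene-presence assignment
#'
#' Standard boolean semantics: a leaf is true iff its gene is in
#' `present_genes`.
#'
#' @param assoc A [gpr] tree or `NULL`. A `NULL` association (no gene
#'   requirement) evaluates to `TRUE`.
#' @param present_genes Character vector of genes considered present.
#' @return Logical scalar.
#' @export
evaluate_gpr <- function(assoc, present_genes) {
  if (is.null(assoc)) return(TRUE)
  rec <- function(node) {
    switch(node$op,
      leaf = node$gene %in% present_genes,
      and = all(vapply(node$children, rec, logical(1))),
      or = any(vapply(node$children, rec, logical(1)))
    )
  }
  rec(assoc)
}

#' Minimal gene sets of a GPR
#'
#' Expands the formula into its list of minimal gene sets: alternative ways to
#' encode the reaction. The reaction is available iff all genes of at least
#' one set are present. Supersets are removed and the list is returned in
#' canonical (lexicographic) order.
#'
#' @param assoc A [gpr] tree or `NULL`.
#' @return A list of character vectors (each sorted); empty list for `NULL`.
#' @examples
#' minimal_gene_sets(parse_gpr("A and (B or C)"))  # {A,B}, {A,C}
#' @export
minimal_gene_sets <- function(assoc) {
  if (is.null(assoc)) return(list())
  rec <- function(node) {
    switch(node$op,
      leaf = list(node$gene),
      or = do.call(c, lapply(node$children, rec)),
      and = {
        sets <- lapply(node$children, rec)
        out <- list(character(0))
        for (s in sets) {
          out <- do.call(c, lapply(out, function(a) {
            lapply(s, function(b) union(a, b))
          }))
        }
        out
      }
    )
  }
  sets <- lapply(rec(assoc), function(s) sort(unique(s)))
  canonical_gene_sets(sets)
}

# de-duplicate, drop supersets, sort lexicographically
canonical_gene_sets <- function(sets) {
  if (length(sets) == 0L) return(list())
  keys <- vapply(sets, paste, character(1), collapse = "\x1f")
  sets <- sets[!duplicated(keys)]
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(sets)) {
    for (b in seq_along(sets)) {
      if (a != b && keep[a] && keep[b] && all(sets[[b]] %in% sets[[a]]) &&
          length(sets[[b]]) < length(sets[[a]])) {
        keep[a] <- FALSE
      }
    }
  }
  sets <- sets[keep]
  sets[order(vapply(sets, paste, character(1), collapse = "\x1f"))]
}

#' Rebuild a GPR from gene sets
#'
#' Inverse of [minimal_gene_sets()]: an OR over AND-terms, one per set.
#'
#' @param sets A list of character vectors of gene ids.
#' @return A [gpr] tree, or `NULL` for an empty list.
#' @export
gene_sets_to_gpr <- function(sets) {
  if (length(sets) == 0L) return(NULL)
  terms <- lapply(sets, function(s) new_gpr_node("and", lapply(s, gpr_leaf)))
  new_gpr_node("or", terms)
}

#' Test two GPRs for truth-table equivalence
#'
#' @param a,b [gpr] trees or `NULL`.
#' @return Logical scalar: equal on every gene-presence assignment.
#' @export
gpr_equivalent <- function(a, b) {
  identical(minimal_gene_sets(a), minimal_gene_sets(b))
}
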