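# Independent oracles used across the suite.

# Truth-table oracle for GPR strings: translates the boolean formula to an R
# expression (R's `&`/`|` precedence matches and/or) and evaluates it under a
# gene-presence assignment, bypassing the package's own tree evaluation.
oracle_eval_gpr_string <- function(text, present) {
  tokens <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  mapped <- vapply(tokens, function(tok) {
    if (tok %in% c("(", ")")) return(tok)
    low <- tolower(tok)
    if (low == "and") return("&")
    if (low == "or") return("|")
    if (tok %in% present) "TRUE" else "FALSE"
  }, character(1))
  eval(parse(text = paste(mapped, collapse = " ")))
}

# All gene-presence assignments of a gene universe (list of character vectors)
all_assignments <- function(genes) {
  n <- length(genes)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    out[[length(out) + 1]] <- genes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  }
  out
}

# checks a GPR tree against the string oracle on every assignment
expect_gpr_matches_oracle <- function(tree, text) {
  genes <- gpr_genes(tree)
  for (present in all_assignments(genes)) {
    expect_identical(
      evaluate_gpr(tree, present),
      oracle_eval_gpr_string(text, present),
      info = paste0("formula '", text, "', present {",
                    paste(present, collapse = ","), "}")
    )
  }
}

# Vertex-enumeration oracle for FBA: enumerates every basic solution of
# {S v = 0, lb <= v <= ub} (n - rank(S) variables fixed at a bound, the rest
# solved for), checks feasibility, and returns the maximal objective value.
oracle_fba_vertex <- function(S, lb, ub, obj_idx, tol = 1e-8) {
  n <- ncol(S)
  r <- qr(S)$rank
  best <- -Inf
  free_sets <- if (r == 0) list(integer(0)) else
    asplit(utils::combn(n, r), 2)
  for (basic in free_sets) {
    basic <- as.integer(basic)
    fixed <- setdiff(seq_len(n), basic)
    # every combination of lower/upper for the fixed variables
    for (mask in 0:(2^length(fixed) - 1)) {
      at_ub <- bitwAnd(mask, 2^(seq_along(fixed) - 1)) > 0
      v <- numeric(n)
      v[fixed] <- ifelse(at_ub, ub[fixed], lb[fixed])
      if (r > 0) {
        rhs <- -as.vector(S[, fixed, drop = FALSE] %*% v[fixed])
        sol <- tryCatch(qr.solve(S[, basic, drop = FALSE], rhs),
                        error = function(e) NULL)
        if (is.null(sol)) next
        v[basic] <- sol
      }
      if (max(abs(S %*% v)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      best <- max(best, v[obj_idx])
    }
  }
  best
}
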