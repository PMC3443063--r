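#' Bounded-variable linear programming by the primal simplex method
#'
#' Solves `maximize c'x  subject to  A x = b,  lb <= x <= ub` with a
#' two-phase bounded-variable simplex. Phase 1 starts from all variables at
#' their lower bounds plus one artificial variable per row and drives the
#' artificials to zero; redundant (rank-deficient) rows simply keep a
#' degenerate artificial in the basis. Bland's smallest-index rule is used
#' for both the entering and the leaving variable, so the method cannot
#' cycle and is fully deterministic. With finite bounds on every structural
#' variable the problem is never unbounded.
#'
#' This is the numerical core behind [fba()] and [flux_variability()]; it is
#' exported for testing against independent oracles.
#'
#' @param c_obj Objective coefficients (length n).
#' @param A Constraint matrix (m x n).
#' @param b Right-hand side (length m).
#' @param lb,ub Finite variable bounds, `lb <= ub`.
#' @param maximize Maximize (default) or minimize.
#' @param tol Feasibility/pivot tolerance.
#' @return List with `status` (`"optimal"` or `"infeasible"`), `x` (the
#'   optimal point, `NULL` if infeasible) and `objective`.
#' @export
lp_bounded <- function(c_obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(c_obj) == n, length(b) == m, length(lb) == n,
            length(ub) == n, all(lb <= ub), all(is.finite(lb)),
            all(is.finite(ub)))
  if (!maximize) c_obj <- -c_obj

  # start: structural variables at lower bound, artificials absorb residuals
  x <- lb
  r <- b - as.vector(A %*% x)
  art_sign <- ifelse(r < 0, -1, 1)
  A_ext <- cbind(A, diag(art_sign, m, m))
  N <- n + m
  lb_e <- c(lb, rep(0, m))
  ub_e <- c(ub, rep(Inf, m))
  x_e <- c(x, abs(r))
  basis <- n + seq_len(m)
  in_basis <- c(rep(FALSE, n), rep(TRUE, m))
  at_upper <- rep(FALSE, N)  # nonbasic status (FALSE = at lower bound)

  run_phase <- function(cost, allow) {
    max_iter <- 200L * (N + 5L)
    for (iter in seq_len(max_iter)) {
      B <- A_ext[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return("singular")
      nonbasic <- which(!in_basis & allow)
      d <- cost[nonbasic] - as.vector(crossprod(A_ext[, nonbasic, drop = FALSE], y))
      enter_ok <- (!at_upper[nonbasic] & d > tol) |
                  (at_upper[nonbasic] & d < -tol)
      # skip nonbasic variables with zero range (cannot move)
      enter_ok <- enter_ok & (ub_e[nonbasic] - lb_e[nonbasic] > tol)
      if (!any(enter_ok)) return("optimal")
      j <- nonbasic[enter_ok][which.min(nonbasic[enter_ok])]  # Bland
      dir <- if (at_upper[j]) -1 else 1
      w <- tryCatch(solve(B, A_ext[, j]), error = function(e) NULL)
      if (is.null(w)) return("singular")
      delta <- dir * w  # x_basis changes by -delta * t

      t_flip <- ub_e[j] - lb_e[j]  # step that flips the entering variable
      lims <- rep(Inf, m)
      for (k in seq_len(m)) {
        bi <- basis[k]
        if (delta[k] > tol) {
          lims[k] <- max(0, (x_e[bi] - lb_e[bi]) / delta[k])
        } else if (delta[k] < -tol) {
          lims[k] <- max(0, (ub_e[bi] - x_e[bi]) / (-delta[k]))
        }
      }
      t_basic <- min(lims)
      t_max <- min(t_flip, t_basic)
      if (!is.finite(t_max)) return("unbounded")
      leave <- 0L  # 0 = bound flip, no basis change
      if (t_basic <= t_flip) {
        ties <- which(lims <= t_basic + tol)
        leave <- ties[which.min(basis[ties])]  # Bland: smallest variable index
      }
      # apply step
      x_e[j] <<- x_e[j] + dir * t_max
      x_e[basis] <<- x_e[basis] - delta * t_max
      if (leave == 0L) {
        at_upper[j] <<- !at_upper[j]  # entering variable flipped bounds
      } else {
        bi <- basis[leave]
        # leaving variable lands on the bound it hit
        hit_lower <- delta[leave] > 0
        x_e[bi] <<- if (hit_lower) lb_e[bi] else ub_e[bi]
        at_upper[bi] <<- !hit_lower
        in_basis[bi] <<- FALSE
        basis[leave] <<- j
        in_basis[j] <<- TRUE
        at_upper[j] <<- FALSE
      }
    }
    "iteration_limit"
  }

  # phase 1: minimize the artificial sum
  cost1 <- c(rep(0, n), rep(-1, m))
  st <- run_phase(cost1, allow = rep(TRUE, N))
  if (st != "optimal" || sum(x_e[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  # phase 2: artificials pinned at zero, structural objective
  ub_e[n + seq_len(m)] <- 0
  x_e[n + seq_len(m)] <- 0
  cost2 <- c(c_obj, rep(0, m))
  st <- run_phase(cost2, allow = c(rep(TRUE, n), rep(FALSE, m)) | in_basis)
  if (st == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  if (st != "optimal") {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  x_out <- pmin(pmax(x_e[seq_len(n)], lb), ub)
  obj <- sum(c_obj * x_out)
  list(status = "optimal", x = x_out,
       objective = if (maximize) obj else -obj)
}
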