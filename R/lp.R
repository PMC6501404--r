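#' Solve a bounded-variable linear program
#'
#' Maximizes (or minimizes) \code{c_obj' x} subject to \code{A x = b} and
#' \code{lb <= x <= ub}, using a dense two-phase primal simplex with explicit
#' lower/upper bound handling (nonbasic variables rest at either bound).
#' Written for the small, fully dense constraint matrices that arise from
#' stoichiometric models of up to a few hundred reactions; the basis is
#' refactorized at every pivot, which is robust and cheap at this scale.
#'
#' Anti-cycling: pivoting starts with the largest-reduced-cost (Dantzig) rule
#' and falls back permanently to Bland's rule once the iteration count passes
#' a degeneracy threshold, which guarantees termination.
#'
#' @param c_obj numeric objective coefficients, length n.
#' @param A constraint matrix (m x n); may have zero rows.
#' @param b right-hand side, length m.
#' @param lb,ub finite variable bounds, length n.
#' @param maximize logical; if \code{FALSE} the objective is minimized.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter hard iteration cap across both phases.
#' @return list with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{objective} and the primal solution \code{x} (all \code{NA} unless
#'   optimal).
#' @keywords internal
solve_lp <- function(c_obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  n <- length(c_obj)
  if (!is.matrix(A)) A <- matrix(A, nrow = length(b), ncol = n)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (!maximize) {
    res <- solve_lp(-c_obj, A, b, lb, ub, TRUE, tol, max_iter)
    if (res$status == "optimal") res$objective <- -res$objective
    return(res)
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  lb <- pmin(lb, ub)  # collapse roundoff-crossed bounds

  if (m == 0L) {
    # pure bound problem
    if (any(c_obj > tol & !is.finite(ub)))
      return(list(status = "unbounded", objective = NA_real_,
                  x = rep(NA_real_, n)))
    x <- ifelse(c_obj > 0, ub, lb)
    return(list(status = "optimal", objective = sum(c_obj * x), x = x))
  }

  # Working arrays cover n structural + m artificial columns.
  N <- n + m
  W <- cbind(A, diag(m))
  wlb <- c(lb, rep(0, m))
  wub <- c(ub, rep(Inf, m))

  # start structural vars at the bound of smaller magnitude
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  r <- b - as.vector(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  W[, (n + 1L):N] <- diag(sgn, m)
  x <- c(x, abs(r))
  basis <- (n + 1L):N
  in_basis <- c(rep(FALSE, n), rep(TRUE, m))

  iter <- 0L
  bland_after <- 100L + 20L * N

  run_phase <- function(cost) {
    repeat {
      iter <<- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached")
      B <- W[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[basis]),
                    error = function(e) stop("singular basis in simplex"))
      nb <- which(!in_basis)
      d <- cost[nb] - as.vector(crossprod(W[, nb, drop = FALSE], y))
      at_lower <- abs(x[nb] - wlb[nb]) <= abs(x[nb] - wub[nb])
      eligible <- (at_lower & d > tol) | (!at_lower & d < -tol)
      # a pinned column (lb == ub) can never move; letting it enter would
      # produce a zero-length bound flip and stall the iteration
      eligible <- eligible & (wub[nb] - wlb[nb]) > 0
      if (!any(eligible)) return("optimal")
      idx <- which(eligible)
      if (iter <= bland_after) {
        j_rel <- idx[which.max(abs(d[idx]))]
      } else {
        j_rel <- idx[1L]  # Bland: smallest index
      }
      j <- nb[j_rel]
      s <- if (at_lower[j_rel]) 1 else -1
      dB <- -s * solve(B, W[, j])

      # ratio test over basic variables plus the entering variable's own span
      t_max <- wub[j] - wlb[j]
      leave <- 0L
      for (k in seq_len(m)) {
        bi <- basis[k]
        if (dB[k] > tol) {
          tk <- (wub[bi] - x[bi]) / dB[k]
        } else if (dB[k] < -tol) {
          tk <- (x[bi] - wlb[bi]) / (-dB[k])
        } else next
        if (tk < t_max - 1e-12) {
          t_max <- tk
          leave <- k
        } else if (tk <= t_max + 1e-12 && leave > 0L && bi < basis[leave]) {
          leave <- k  # tie-break on smallest variable index (Bland-safe)
        }
      }
      if (!is.finite(t_max)) return("unbounded")
      t_max <- max(t_max, 0)

      x[j] <<- x[j] + s * t_max
      x[basis] <<- x[basis] + t_max * dB
      if (leave == 0L) {
        # bound flip, basis unchanged
        next
      }
      out <- basis[leave]
      # snap the leaving variable onto the bound it hit
      x[out] <<- if (dB[leave] > 0) wub[out] else wlb[out]
      in_basis[out] <<- FALSE
      in_basis[j] <<- TRUE
      basis[leave] <<- j
    }
  }

  # Phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(-1, m))
  st <- run_phase(cost1)
  if (st != "optimal" || sum(x[(n + 1L):N]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  # Phase 2: pin artificials and optimize the real objective
  wub[(n + 1L):N] <- 0
  x[(n + 1L):N] <- pmin(x[(n + 1L):N], 0)
  x[(n + 1L):N] <- pmax(x[(n + 1L):N], 0)
  cost2 <- c(c_obj, rep(0, m))
  st <- run_phase(cost2)
  if (st == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  xs <- pmin(pmax(x[seq_len(n)], lb), ub)
  list(status = "optimal", objective = sum(c_obj * xs), x = xs)
}

#' Feasibility check for A x = b, lb <= x <= ub
#' @return logical scalar; attribute "x" holds a feasible point when TRUE.
#' @keywords internal
lp_feasible <- function(A, b, lb, ub, tol = 1e-9) {
  res <- solve_lp(rep(0, length(lb)), A, b, lb, ub, maximize = TRUE, tol = tol)
  ok <- identical(res$status, "optimal")
  structure(ok, x = if (ok) res$x else NULL)
}
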