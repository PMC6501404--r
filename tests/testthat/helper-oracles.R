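# Independent oracles used to cross-check the package's own solvers.

# LP oracle via boot::simplex (recommended package, independent simplex
# implementation). Variables are shifted to x = v - lb >= 0 and equality
# rows with negative right-hand side are sign-flipped, as boot::simplex
# requires non-negative b vectors.
oracle_lp_boot <- function(cv, A, b, lb, ub, maximize = TRUE) {
  n <- length(cv)
  b3 <- b - as.vector(A %*% lb)
  A3 <- A
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, , drop = FALSE]
  b3[neg] <- -b3[neg]
  res <- tryCatch(
    boot::simplex(a = cv, A1 = diag(n), b1 = ub - lb, A3 = A3, b3 = b3,
                  maxi = maximize, eps = 1e-10),
    error = function(e) NULL)
  if (is.null(res) || res$solved != 1) return(NULL)
  list(objective = unname(res$value + sum(cv * lb)), x = unname(res$soln + lb))
}

# Exhaustive vertex-enumeration oracle for max c'x s.t. Ax = b, lb<=x<=ub.
# Every vertex has >= n - m variables at a bound; enumerate basic sets and
# bound assignments. Only suitable for n <= ~10.
oracle_lp_enum <- function(cv, A, b, lb, ub) {
  n <- length(cv); m <- nrow(A)
  best <- -Inf; found <- FALSE
  check_point <- function(x) {
    if (all(x >= lb - 1e-7) && all(x <= ub + 1e-7) &&
        max(abs(A %*% x - b)) < 1e-7) {
      found <<- TRUE
      best <<- max(best, sum(cv * x))
    }
  }
  if (m == 0L) {
    check_point(ifelse(cv > 0, ub, lb))
    return(if (found) best else NULL)
  }
  combs <- utils::combn(n, min(m, n))
  for (ci in seq_len(ncol(combs))) {
    B <- combs[, ci]
    NB <- setdiff(seq_len(n), B)
    Bm <- A[, B, drop = FALSE]
    if (nrow(Bm) != length(B)) next
    if (abs(det(Bm)) < 1e-10) next
    k <- length(NB)
    for (mask in 0:(2^k - 1)) {
      xn <- if (k) ifelse(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0,
                          ub[NB], lb[NB]) else numeric(0)
      rhs <- b - (if (k) as.vector(A[, NB, drop = FALSE] %*% xn) else 0)
      xb <- solve(Bm, rhs)
      x <- numeric(n); x[NB] <- xn; x[B] <- xb
      check_point(x)
    }
  }
  if (found) best else NULL
}

# Truth-table oracle for GPR deletion semantics: renders the rule as an R
# boolean expression and evaluates it with base R's own and/or.
oracle_gpr_eval <- function(rule, deleted) {
  txt <- function(r) {
    if (r$op == "gene") return(if (r$gene %in% deleted) "FALSE" else "TRUE")
    op <- if (r$op == "and") " & " else " | "
    paste0("(", paste(vapply(r$children, txt, ""), collapse = op), ")")
  }
  eval(parse(text = txt(rule)))
}

# Independent min/max recursion for expression-state mapping, written over
# the deparsed expression string rather than the tree.
oracle_state_eval <- function(rule, states) {
  txt <- function(r) {
    if (r$op == "gene") {
      s <- states[r$gene]
      return(sprintf("%d", if (is.na(s)) 0L else as.integer(s)))
    }
    fn <- if (r$op == "and") "min" else "max"
    paste0(fn, "(", paste(vapply(r$children, txt, ""), collapse = ","), ")")
  }
  eval(parse(text = txt(rule)))
}

# random GPR tree with n_leaves leaves over the given gene pool
random_gpr <- function(n_leaves, genes) {
  if (n_leaves == 1L) return(gpr_gene(sample(genes, 1)))
  k <- sample.int(n_leaves - 1L, 1L)
  node <- list(op = sample(c("and", "or"), 1),
               children = list(random_gpr(k, genes),
                               random_gpr(n_leaves - k, genes)))
  node
}

# matrix-based dead-end oracle: a non-boundary metabolite is a dead end
# unless some reaction can produce it and some reaction can consume it
oracle_dead_ends <- function(model) {
  S <- stoich_matrix(model)
  bd <- gsmmr:::reaction_bounds(model)
  fwd <- bd$ub > 0; bwd <- bd$lb < 0
  can_prod <- (S > 0) %*% diag(as.numeric(fwd), length(fwd)) +
    (S < 0) %*% diag(as.numeric(bwd), length(bwd))
  can_cons <- (S < 0) %*% diag(as.numeric(fwd), length(fwd)) +
    (S > 0) %*% diag(as.numeric(bwd), length(bwd))
  rownames(S)[!(rowSums(can_prod) > 0 & rowSums(can_cons) > 0)]
}

# tiny linear-chain model: EX -> M1 -> ... -> biomass, unit yields
chain_model <- function(n = 3, uptake = 10) {
  spec <- synthetic_spec(seed = 1, topology = "chain", n_segments = n,
                         uptake = uptake)
  make_random_model(spec)
}

# diamond toy: two equivalent parallel branches between stem reactions
diamond_toy <- function(uptake = 10) {
  rx <- list(
    reaction("EX_A", c(A_e = -1, A_b = 1), lb = -uptake, ub = 1000,
             subsystem = "Exchange"),
    reaction("S1", c(A_e = -1, M_c = 1)),
    reaction("B1", c(M_c = -1, N_c = 1)),
    reaction("B2", c(M_c = -1, N_c = 1)),
    reaction("BIOMASS", c(N_c = -1, biomass_e = 1)),
    reaction("EX_biomass", c(biomass_e = -1, biomass_b = 1), lb = 0,
             ub = 1000, subsystem = "Exchange"))
  m <- metabolic_model(gsmmr:::build_metabolite_table(rx), rx,
                       objective = "BIOMASS")
  validate_model(m)
  m
}

# RPKM values printed for the transporter/glycerol-pathway genes
printed_rpkm <- function() {
  expression_table(matrix(
    c(80.23, 967.20, 188.36,
      59.20, 71.28, 4535.25,
      28.10, 30.78, 1683.89),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("SMDB11_0473", "SMDB11_4022", "SMDB11_3886"),
                    c("glucose", "GlcNAc", "glycerol"))))
}
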