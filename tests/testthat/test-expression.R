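test_that("the geometric bin grid is the exponential ladder of its base", {
  grid <- build_bin_grid(base = 1.2, n = 58)
  expect_equal(grid$cutoffs[1], 1.0)
  expect_length(grid$cutoffs, 58L)
  expect_true(all(diff(grid$cutoffs) > 0))
  expect_equal(unique(round(grid$cutoffs[-1] / grid$cutoffs[-58], 12)), 1.2)
  # the upper discretization threshold sits at grid index 37
  expect_equal(round(grid$cutoffs[38], 2), 850.56)
  expect_error(build_bin_grid(base = 1), "base")
  expect_error(build_bin_grid(n = 1), "n must")
})

test_that("lower-cutoff selection finds the planted 10% quantile", {
  spec <- synthetic_spec(seed = 5, target_low_fraction = 0.10)
  tab <- make_expression_table(paste0("g", 1:5000), spec)
  cut <- select_lower_cutoff(tab, target_fraction = 0.10)
  # the planted quantile sits between grid points 1.2^5 and 1.2^6, so the
  # selected cutoff is the grid value that rounds to the canonical 3.00
  expect_equal(round(as.numeric(cut), 1), 3.0, tolerance = 0.11)
  expect_gte(attr(cut, "achieved_fraction"), 0.10)
  # target 0 returns the first cutoff
  cut0 <- select_lower_cutoff(tab, target_fraction = 0)
  expect_equal(as.numeric(cut0), 1.0)
  expect_error(select_lower_cutoff(tab[0, , drop = FALSE]), "empty")
})

test_that("discretization follows the two-threshold rule with its boundaries", {
  thr <- discretization_thresholds(3.00, 850.56)
  expect_identical(discretize_gene(0, thr), -1L)           # g = 0 is low
  expect_identical(discretize_gene(2.99, thr), -1L)
  expect_identical(discretize_gene(3.00, thr), 0L)         # boundary -> moderate
  expect_identical(discretize_gene(850.56, thr), 0L)       # boundary -> moderate
  expect_identical(discretize_gene(850.57, thr), 1L)
  expect_identical(discretize_gene(967.20, thr), 1L)       # the GlcNAc transporter
  expect_error(discretize_gene(-1, thr), ">= 0")
  expect_error(discretization_thresholds(5, 2), "gamma_low < gamma_high")
})

test_that("discretization partitions genes and is monotone in gamma_high", {
  set.seed(88)
  g <- c(0, rlnorm(500, 4, 2))
  st <- discretize_gene(g)
  expect_length(st, length(g))
  counts <- table(factor(st, c(-1, 0, 1)))
  expect_equal(sum(counts), length(g))
  # raising gamma_high never increases the number of high genes
  highs <- vapply(c(100, 300, 850.56, 2000),
                  function(gh) sum(discretize_gene(
                    g, discretization_thresholds(3, gh)) == 1L), integer(1))
  expect_true(all(diff(highs) <= 0))
})

test_that("fold changes reproduce the printed RPKM ratios", {
  tab <- printed_rpkm()
  expect_equal(fold_change(tab, "SMDB11_4022", "glycerol", "glucose",
                           digits = 1), 76.6)
  expect_equal(fold_change(tab, "SMDB11_3886", "glycerol", "glucose",
                           digits = 1), 59.9)
  expect_equal(fold_change(tab, "SMDB11_0473", "GlcNAc", "glycerol",
                           digits = 2), 5.13)
  expect_equal(fold_change(tab, "SMDB11_0473", "GlcNAc", "GlcNAc"), 1.0)
  tab0 <- expression_table(matrix(c(5, 0), 1, 2,
                                  dimnames = list("g", c("a", "b"))))
  expect_warning(fc <- fold_change(tab0, "g", "a", "b"), "infinite")
  expect_identical(fc, Inf)
})

test_that("clamp mode zeroes low reactions and extends high capacity", {
  m <- make_toy_core_model()
  tab <- make_toy_expression_profiles(m)
  st <- gene_states(tab, "GlcNAc")
  m2 <- apply_expression_constraints(m, st, mode = "clamp")
  rs <- attr(m2, "reaction_states")
  expect_identical(unname(rs[c("CS")]), -1L)
  expect_equal(c(m2$reactions$CS$lb, m2$reactions$CS$ub), c(0, 0))
  # soundness: clamped reactions carry zero flux in every feasible solution
  rng <- solve_fva(m2, fraction = 0, reactions = names(rs)[rs == -1L])
  expect_true(all(abs(rng$min) < 1e-9 & abs(rng$max) < 1e-9))
  # high state extends capacity (glucose condition: gCS is high)
  st_glc <- gene_states(tab, "glucose")
  m3 <- apply_expression_constraints(m, st_glc, mode = "clamp")
  expect_equal(m3$reactions$CS$ub, 1000)
  # all-moderate states leave the model untouched
  st0 <- structure(rep(0L, length(m$genes)), names = m$genes)
  m4 <- apply_expression_constraints(m, st0, mode = "clamp")
  expect_equal(solve_fba(m4)$objective, solve_fba(m)$objective)
  for (id in names(m$reactions)) {
    expect_equal(m4$reactions[[id]]$lb, m$reactions[[id]]$lb)
    expect_equal(m4$reactions[[id]]$ub, m$reactions[[id]]$ub)
  }
})

test_that("clamping the sole biomass path kills growth; biomass is never clamped", {
  m <- chain_model(3)
  g1 <- attr(m, "ground_truth_essentials")[1]
  st <- structure(rep(0L, length(m$genes)), names = m$genes)
  st[g1] <- -1L
  m2 <- apply_expression_constraints(m, st, mode = "clamp")
  expect_equal(solve_fba(m2)$objective, 0, tolerance = 1e-9)
  # biomass state -1 raises a warning and is left unclamped
  m3 <- make_toy_core_model()
  m3$reactions$BIOMASS$gpr <- gpr_gene("gBM")
  m3$genes <- sort(c(m3$genes, "gBM"))
  stb <- structure(rep(0L, length(m3$genes)), names = m3$genes)
  stb["gBM"] <- -1L
  expect_warning(m4 <- apply_expression_constraints(m3, stb, mode = "clamp"),
                 "biomass")
  expect_gt(m4$reactions$BIOMASS$ub, 0)
})

test_that("iMAT optimum equals exhaustive indicator-assignment search", {
  # independent oracle: enumerate every satisfy/miss assignment, check
  # feasibility with boot::simplex, take the best score
  oracle_imat <- function(model, states, eps = 1) {
    rs <- gsmmr:::reaction_states(model, states)
    S <- stoich_matrix(model)
    bd <- gsmmr:::reaction_bounds(model)
    dec <- sort(names(rs)[rs != 0L])
    opts <- lapply(dec, function(id) {
      i <- match(id, bd$id)
      if (rs[[id]] == 1L) {
        o <- list(list(lb = eps, ub = bd$ub[i], sat = TRUE))
        if (bd$lb[i] <= -eps)
          o <- c(o, list(list(lb = bd$lb[i], ub = -eps, sat = TRUE)))
        c(o, list(list(lb = bd$lb[i], ub = bd$ub[i], sat = FALSE)))
      } else {
        list(list(lb = max(bd$lb[i], -eps), ub = min(bd$ub[i], eps),
                  sat = TRUE),
             list(lb = bd$lb[i], ub = bd$ub[i], sat = FALSE))
      }
    })
    best <- -1L
    grid <- do.call(expand.grid, lapply(opts, seq_along))
    for (row in seq_len(nrow(grid))) {
      lb <- bd$lb; ub <- bd$ub; sc <- 0L
      for (k in seq_along(dec)) {
        ch <- opts[[k]][[grid[row, k]]]
        i <- match(dec[k], bd$id)
        lb[i] <- ch$lb; ub[i] <- ch$ub
        sc <- sc + ch$sat
      }
      if (sc <= best) next
      if (!is.null(oracle_lp_boot(rep(0, length(lb)), S, rep(0, nrow(S)),
                                  lb, ub)))
        best <- sc
    }
    best
  }
  m <- diamond_toy()
  m$reactions$B1$gpr <- gpr_gene("gb1")
  m$reactions$B2$gpr <- gpr_gene("gb2")
  m$reactions$S1$gpr <- gpr_gene("gs")
  m$genes <- c("gb1", "gb2", "gs")
  cases <- list(c(gb1 = 1L, gb2 = -1L, gs = 0L),
                c(gb1 = 1L, gb2 = 1L, gs = -1L),
                c(gb1 = -1L, gb2 = -1L, gs = 1L),
                c(gb1 = 1L, gb2 = 1L, gs = 1L))
  for (st in cases) {
    prob <- apply_expression_constraints(m, st, mode = "imat")
    res <- solve_imat(prob)
    expect_identical(res$status, "optimal")
    expect_equal(res$score, oracle_imat(m, st), label = paste(st, collapse = ","))
    # witness fluxes honor the satisfied indicators
    sat <- names(res$satisfied)[res$satisfied]
    rs <- prob$reaction_states
    for (id in sat) {
      if (rs[[id]] == 1L) expect_gte(abs(res$fluxes[[id]]), 1 - 1e-7)
      else expect_lte(abs(res$fluxes[[id]]), 1 + 1e-7)
    }
  }
})

test_that("iMAT agreement is bounded and attains the bound when satisfiable", {
  m <- make_toy_core_model()
  tab <- make_toy_expression_profiles(m)
  st <- gene_states(tab, "glucose")     # single high gene, satisfiable
  prob <- apply_expression_constraints(m, st, mode = "imat")
  res <- solve_imat(prob)
  expect_lte(res$score, res$n_constrained)
  expect_equal(res$score, res$n_constrained)
})

test_that("active-reaction accounting partitions by subsystem", {
  m <- make_toy_core_model()
  sol <- solve_fba(m)
  rep <- active_reaction_report(m, sol)
  expect_equal(sum(rep$count), attr(rep, "total"))
  expect_true("Citrate cycle (TCA cycle)" %in% rep$subsystem)
  # zero solution: no active reactions
  m0 <- make_toy_core_model()
  m0$reactions$EX_glc$lb <- 0
  rep0 <- active_reaction_report(m0, solve_fba(m0))
  expect_equal(attr(rep0, "total"), 0L)
})

test_that("condition comparison silences the TCA branch under GlcNAc", {
  m <- make_toy_core_model()
  tab <- make_toy_expression_profiles(m)
  reports <- lapply(c("glucose", "GlcNAc"), function(cond) {
    m2 <- apply_expression_constraints(m, gene_states(tab, cond),
                                       mode = "clamp")
    sol <- solve_fba(m2)
    list(sol = sol, rep = active_reaction_report(m2, sol))
  })
  names(reports) <- c("glucose", "GlcNAc")
  tca <- attr(m, "tca_reactions")
  ppp <- attr(m, "ppp_reactions")
  glc_active <- attr(reports$glucose$rep, "active")
  nag_active <- attr(reports$GlcNAc$rep, "active")
  # glucose: TCA fully active; GlcNAc: TCA silent, pentose branch persists
  expect_true(all(tca %in% glc_active))
  expect_false(any(tca %in% nag_active))
  expect_true(all(ppp %in% nag_active))
  expect_gt(reports$GlcNAc$sol$objective, 0)
})
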