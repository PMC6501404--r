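test_that("a linear chain yields its analytic 1:1 optimum", {
  m <- chain_model(n = 3, uptake = 10)
  sol <- solve_fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-8)
  # every chain reaction carries the full flux at fraction 1: no degeneracy
  rng <- solve_fva(m, fraction = 1)
  expect_true(all(abs(rng$min - rng$max) < 1e-7))
})

test_that("nothing in means nothing out: closed exchanges give zero growth", {
  m <- chain_model(n = 3, uptake = 10)
  m$reactions$EX_sub$lb <- 0
  sol <- solve_fba(m)
  expect_equal(sol$objective, 0, tolerance = 1e-9)
})

test_that("optimal solutions satisfy mass balance and bounds", {
  for (s in 1:8) {
    m <- make_random_model(synthetic_spec(seed = s, n_segments = 5))
    sol <- solve_fba(m)
    expect_identical(sol$status, "optimal")
    S <- stoich_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    bd <- gsmmr:::reaction_bounds(m)
    expect_true(all(sol$fluxes >= bd$lb - 1e-7 &
                      sol$fluxes <= bd$ub + 1e-7))
  }
})

test_that("FBA optimum matches vertex enumeration on small networks", {
  # toys with <= 8 reactions, exhaustively enumerated
  toys <- list(chain_model(2), chain_model(3), diamond_toy(),
               make_random_model(synthetic_spec(seed = 9, topology = "chain",
                                                n_segments = 4)))
  for (m in toys) {
    S <- stoich_matrix(m)
    bd <- gsmmr:::reaction_bounds(m)
    cv <- as.numeric(bd$id == m$objective)
    ref <- oracle_lp_enum(cv, S, rep(0, nrow(S)), bd$lb, bd$ub)
    expect_false(is.null(ref))
    expect_equal(solve_fba(m)$objective, ref, tolerance = 1e-6)
  }
})

test_that("doubling the carbon uptake doubles the optimum on a linear toy", {
  z1 <- solve_fba(chain_model(3, uptake = 5))$objective
  z2 <- solve_fba(chain_model(3, uptake = 10))$objective
  expect_equal(z2, 2 * z1, tolerance = 1e-8)
  z3 <- attr(make_toy_core_model(uptake = 20), "optimal_growth")
  expect_equal(solve_fba(make_toy_core_model(uptake = 20))$objective, z3,
               tolerance = 1e-8)
})

test_that("FVA brackets the FBA solution and collapses on a single path", {
  m <- make_toy_core_model()
  sol <- solve_fba(m)
  rng <- solve_fva(m, fraction = 1)
  v <- sol$fluxes[rng$id]
  expect_true(all(rng$min <= v + 1e-6 & v <= rng$max + 1e-6))
  expect_true(all(rng$min <= rng$max + 1e-9))
  bd <- gsmmr:::reaction_bounds(m)
  expect_true(all(rng$min >= bd$lb[match(rng$id, bd$id)] - 1e-7))
  expect_true(all(rng$max <= bd$ub[match(rng$id, bd$id)] + 1e-7))
})

test_that("diamond branches split the optimum between equivalent routes", {
  m <- diamond_toy(uptake = 10)
  rng <- solve_fva(m, fraction = 1)
  for (id in c("B1", "B2")) {
    expect_equal(rng$min[rng$id == id], 0, tolerance = 1e-7)
    expect_equal(rng$max[rng$id == id], 10, tolerance = 1e-7)
  }
  # the stem is pinned at the optimum
  expect_equal(rng$min[rng$id == "S1"], 10, tolerance = 1e-7)
  # flux-minimized reported solution still sums branches to the optimum
  sol <- solve_fba(m)
  expect_equal(unname(sol$fluxes["B1"] + sol$fluxes["B2"]), 10,
               tolerance = 1e-7)
})

test_that("FVA at fraction 0 equals raw reachable ranges (enumeration)", {
  m <- diamond_toy(uptake = 10)
  rng <- solve_fva(m, fraction = 0)
  S <- stoich_matrix(m)
  bd <- gsmmr:::reaction_bounds(m)
  for (k in seq_along(bd$id)) {
    cv <- as.numeric(seq_along(bd$id) == k)
    hi <- oracle_lp_enum(cv, S, rep(0, nrow(S)), bd$lb, bd$ub)
    lo <- -oracle_lp_enum(-cv, S, rep(0, nrow(S)), bd$lb, bd$ub)
    expect_equal(rng$max[rng$id == bd$id[k]], hi, tolerance = 1e-6)
    expect_equal(rng$min[rng$id == bd$id[k]], lo, tolerance = 1e-6)
  }
  expect_error(solve_fva(m, fraction = 1.5), "fraction")
  expect_error(solve_fva(m, fraction = -0.1), "fraction")
})

test_that("apply_medium closes all uptakes except listed components", {
  m <- make_toy_core_model()
  m2 <- apply_medium(m, medium_spec(c(glc = 10.53), "glc"))
  expect_equal(m2$reactions$EX_glc$lb, -10.53)
  expect_equal(solve_fba(m2)$objective, 10.53 / 2, tolerance = 1e-7)
  # a medium without usable carbon closes the glucose uptake: no growth
  m3 <- apply_medium(m, medium_spec(c(co2 = 0), "co2"))
  expect_equal(solve_fba(m3)$objective, 0, tolerance = 1e-9)
  expect_error(
    apply_medium(make_toy_core_model(),
                 medium_spec(c(unobtainium = 1), "unobtainium")),
    "no exchange reaction: unobtainium")
})

test_that("the minimal medium carries the published component set", {
  med <- minimal_medium("glc", 10.53)
  expect_setequal(names(med$components),
                  c("h2o", "nh4", "so4", "pi", "ca2", "fe3", "h2s", "k",
                    "mg2", "pnto-r", "nmn", "glc"))
  expect_equal(med$components[["glc"]], 10.53)
  expect_identical(med$carbon_source, "glc")
  expect_error(medium_spec(c(glc = -1), "glc"), ">= 0")
  expect_error(medium_spec(c(glc = 1), "xyl"), "member")
})

test_that("a never-consumed medium component leaves the optimum unchanged", {
  m <- chain_model(3, uptake = 10)
  z0 <- solve_fba(m)$objective
  # open an irrelevant uptake by adding a dead exchange
  m$reactions[["EX_x"]] <- reaction("EX_x", c(x_e = -1, x_b = 1),
                                    lb = -50, ub = 1000,
                                    subsystem = "Exchange")
  m$metabolites <- gsmmr:::build_metabolite_table(m$reactions)
  expect_equal(solve_fba(m)$objective, z0, tolerance = 1e-9)
})

test_that("measured-exchange windows pin fluxes or surface infeasibility", {
  m <- make_toy_core_model()
  # pin glucose exchange exactly; FVA range collapses to the point
  m2 <- constrain_measured_exchanges(m, c(EX_glc = -8))
  rng <- solve_fva(m2, fraction = 1, reactions = "EX_glc")
  expect_equal(rng$min, -8, tolerance = 1e-7)
  expect_equal(rng$max, -8, tolerance = 1e-7)
  expect_equal(solve_fba(m2)$objective, 4, tolerance = 1e-7)
  # a window around the measurement keeps it inside
  m3 <- constrain_measured_exchanges(
    m, data.frame(id = "EX_glc", value = -8, tol = 1))
  expect_equal(m3$reactions$EX_glc$lb, -9)
  expect_equal(m3$reactions$EX_glc$ub, -7)
  # over-constrained by conservation: forced secretion without any uptake
  m4 <- constrain_measured_exchanges(
    make_toy_core_model(),
    data.frame(id = c("EX_glc", "EX_etoh"), value = c(0, 5), tol = 0))
  expect_identical(solve_fba(m4)$status, "infeasible")
  expect_error(constrain_measured_exchanges(
    m, data.frame(id = "EX_glc", value = 0, tol = -1)), ">= 0")
})

test_that("dead-end detection flags a chain missing its sink", {
  m <- parse_model_file(c("EX_A: A_e <=> A_b",
                          "R1: A_e --> B_c",
                          "R2: B_c --> C_c"))
  de <- find_dead_end_metabolites(m)
  expect_true("C_c" %in% de)      # only produced
  expect_false("B_c" %in% de)
  blocked <- find_blocked_reactions(m)
  expect_setequal(blocked, c("R1", "R2", "EX_A"))
  # fully connected toy: nothing flagged
  m2 <- make_toy_core_model()
  expect_length(find_dead_end_metabolites(m2), 0L)
  expect_length(find_blocked_reactions(m2), 0L)
})

test_that("dead-end detection agrees with the matrix oracle on random models", {
  set.seed(77)
  for (s in 1:10) {
    m <- make_random_model(synthetic_spec(seed = s, n_segments = 8))
    # randomly prune some reactions to create gaps
    drop <- sample(setdiff(names(m$reactions),
                           c("BIOMASS", "EX_sub", "EX_biomass")),
                   size = min(2L, length(m$reactions) - 3L))
    m$reactions[drop] <- NULL
    m$metabolites <- gsmmr:::build_metabolite_table(m$reactions)
    expect_setequal(find_dead_end_metabolites(m), oracle_dead_ends(m))
  }
})
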