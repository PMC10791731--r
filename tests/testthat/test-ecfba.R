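# Unit bridging, measured-rate bounds, the pooled enzyme-capacity
# constraint, and the FBA/pFBA solver against the enumeration oracle.

test_that("per-cell rates convert to gDCW-specific fluxes", {
  expect_equal(per_cell_to_specific(1, 250), 1 / 6, tolerance = 1e-12)
  expect_equal(per_cell_to_specific(0), 0)
  expect_equal(per_cell_to_specific(-2.4, 250), -0.4, tolerance = 1e-12)
  expect_error(per_cell_to_specific(1, 0), "positive")
})

test_that("measured bands relax by the magnitude fraction", {
  rc <- rate_constraints(c(EX_a = -1, EX_b = 0.5, EX_c = 0))
  expect_equal(rc$lb[1], -1.2); expect_equal(rc$ub[1], -0.8)
  expect_equal(rc$lb[2], 0.4); expect_equal(rc$ub[2], 0.6)
  expect_equal(rc$lb[3], -1e-6); expect_equal(rc$ub[3], 1e-6)  # zero-rate floor
  rc0 <- rate_constraints(c(EX_a = -1), relaxation = 0)
  expect_equal(rc0$lb, rc0$ub)
  m <- tiny_branch_model()
  expect_error(apply_rate_bounds(m, c(EX_missing = -1)), "no such exchange")
  m2 <- apply_rate_bounds(m, c(EX_A = -1))
  expect_equal(m2$reactions[["EX_A"]]$lb, -1.2)
  expect_equal(m2$reactions[["EX_A"]]$ub, -0.8)
})

test_that("a single-reaction capacity row caps flux at P_total*kcat/MW", {
  mets <- data.frame(id = c("a[c]", "b[c]"), name = c("a", "b"),
                     compartment = "c")
  rxns <- list(
    reaction("EX_a", c("a[c]" = -1), lb = -10, ub = 0),
    reaction("AB", c("a[c]" = -1, "b[c]" = 1), kcat = 1, mw = 2),  # MW/kcat = 2
    reaction("EX_b", c("b[c]" = -1)))
  m <- metabolic_model(mets, rxns, objective = "EX_b")
  m <- apply_enzyme_capacity(m, 1)
  s <- solve_fba(m)
  expect_equal(s$objective_value, 0.5, tolerance = 1e-9)
  m_inf <- apply_enzyme_capacity(m, Inf)
  expect_equal(solve_fba(m_inf)$objective_value, 10, tolerance = 1e-9)
})

test_that("capacity constraint is skipped with a warning when unannotated", {
  m <- tiny_branch_model()
  expect_warning(m2 <- apply_enzyme_capacity(m, 0.1), "no kcat/MW")
  expect_true(is.na(m2$p_total))
})

test_that("tightening the enzyme budget is monotone in the biomass optimum", {
  m <- toy_cho_network()
  sweep <- c(0.004, 0.008, 0.016, 0.032, 0.064)
  opt <- vapply(sweep, function(pt)
    solve_fba(apply_enzyme_capacity(m, pt), pfba = FALSE)$objective_value,
    numeric(1))
  expect_true(all(diff(opt) >= -1e-9))     # non-decreasing in the budget
  expect_gt(opt[5], opt[1] + 0.01)         # and genuinely binding below
})

test_that("LP optimum matches exhaustive enumeration on a tiny network", {
  m <- tiny_branch_model()
  ms <- split_reversible(m)
  S <- stoich_matrix(ms)
  lb <- reaction_field(ms, "lb"); ub <- reaction_field(ms, "ub")
  cc <- as.numeric(names(ms$reactions) == "EX_C")
  ref <- lp_enumerate(cc, S, rep(0, nrow(S)), lb, ub)
  s <- solve_fba(m, pfba = FALSE)
  expect_equal(s$objective_value, ref$value, tolerance = 1e-9)
  # BC capacity 4 binds: optimum is min(uptake 10, BC cap 4)
  expect_equal(s$objective_value, 4, tolerance = 1e-12)
})

test_that("solutions satisfy steady state and bounds; parsimony is unique", {
  m <- augment_with_gy(toy_cho_network())
  s1 <- solve_fba(m)
  s2 <- solve_fba(m)
  expect_identical(s1$fluxes, s2$fluxes)
  S <- stoich_matrix(s1$model)
  expect_lt(max(abs(S %*% s1$fluxes)), 1e-6)
  lb <- reaction_field(s1$model, "lb"); ub <- reaction_field(s1$model, "ub")
  expect_true(all(s1$fluxes >= lb - 1e-8) && all(s1$fluxes <= ub + 1e-8))
  ## the parsimonious vector is never larger than the plain optimum's
  s_plain <- solve_fba(m, pfba = FALSE)
  expect_lte(s1$total_flux, s_plain$total_flux + 1e-9)
  expect_equal(s1$objective_value, s_plain$objective_value, tolerance = 1e-8)
})

test_that("fixing the antibody flux trades off against biomass", {
  m <- toy_cho_network()
  s0 <- solve_ecfba(m, igg_flux = 0)
  s1 <- solve_ecfba(m, igg_flux = 0.02)
  expect_gte(s0$objective_value, s1$objective_value)
  expect_equal(s1$fluxes[["IGGSYN"]], 0.02, tolerance = 1e-9)
  expect_error(solve_ecfba(m, igg_flux = -1), "non-negative")
  ## optional growth cap binds
  s2 <- solve_ecfba(m, igg_flux = 0, growth_cap = 0.01)
  expect_lte(s2$objective_value, 0.01 + 1e-9)
})

test_that("condition averaging equals the single solution for identical reps", {
  m <- augment_with_gy(toy_cho_network())
  rates <- c("EX_glc_D(e)" = -0.1, "EX_lac_L(e)" = 0.09, "EX_glytyr(e)" = -0.01)
  one <- solve_ecfba(apply_rate_bounds(m, rates), 0.02)
  avg <- condition_flux(m, list(rates, rates), c(0.02, 0.02))
  expect_equal(avg$fluxes, one$fluxes, tolerance = 1e-10)
  expect_equal(avg$n_replicates, 2)
})

test_that("infeasible replicates are skipped with a warning", {
  m <- augment_with_gy(toy_cho_network())
  good <- c("EX_glc_D(e)" = -0.1, "EX_lac_L(e)" = 0.09)
  bad <- c("EX_glc_D(e)" = 0.5)    # forced glucose secretion: impossible
  expect_warning(avg <- condition_flux(m, list(good, bad), c(0.02, 0.02)),
                 "infeasible")
  expect_equal(avg$n_replicates, 1)
  expect_error(
    suppressWarnings(condition_flux(m, list(bad), 0.02)),
    "all replicates infeasible")
})

test_that("perturbed-uptake averages stay within the replicate envelope", {
  m <- augment_with_gy(toy_cho_network())
  r1 <- c("EX_glc_D(e)" = -0.11, "EX_lac_L(e)" = 0.09)
  r2 <- c("EX_glc_D(e)" = -0.09, "EX_lac_L(e)" = 0.09)
  s1 <- solve_ecfba(apply_rate_bounds(m, r1), 0.02)
  s2 <- solve_ecfba(apply_rate_bounds(m, r2), 0.02)
  avg <- condition_flux(m, list(r1, r2), c(0.02, 0.02))
  lo <- pmin(s1$fluxes, s2$fluxes) - 1e-9
  hi <- pmax(s1$fluxes, s2$fluxes) + 1e-9
  expect_true(all(avg$fluxes >= lo & avg$fluxes <= hi))
})
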