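# Model container, format round-trips, dipeptide augmentation, the antibody
# reaction, reversible splitting and the reduced network's structure.

test_that("invalid models are rejected with informative errors", {
  mets <- data.frame(id = "a[c]", name = "a", compartment = "c")
  expect_error(
    metabolic_model(mets, list(reaction("R1", c("b[c]" = 1)))),
    "unknown metabolites")
  expect_error(reaction("R0", c()), "empty stoichiometry")
  expect_error(reaction("R0", c("a[c]" = 1), lb = 2, ub = 1), "lb > ub")
  expect_error(
    metabolic_model(data.frame(id = "a[c]", name = "a", compartment = "m"),
                    list(reaction("R1", c("a[c]" = 1)))),
    "compartment tag")
})

test_that("the fixture network round-trips through JSON losslessly", {
  m <- toy_cho_network()
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model(path)
  expect_identical(stoich_matrix(m), stoich_matrix(m2))
  expect_identical(reaction_table(m), reaction_table(m2))
  expect_identical(m$objective, m2$objective)
  expect_identical(m$p_total, m2$p_total)
})

test_that("SBML export re-imports with the identical stoichiometric matrix", {
  m <- augment_with_gy(toy_cho_network())
  path <- tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  S1 <- stoich_matrix(m)
  S2 <- stoich_matrix(m2)
  expect_identical(sort(rownames(S1)), sort(rownames(S2)))
  expect_identical(sort(colnames(S1)), sort(colnames(S2)))
  expect_equal(S2[rownames(S1), colnames(S1)], S1)
  rt <- reaction_table(m); rt2 <- reaction_table(m2)
  rt2 <- rt2[match(rt$id, rt2$id), ]
  expect_equal(rt$lb, rt2$lb)
  expect_equal(rt$ub, rt2$ub)
  expect_equal(rt$reversible, rt2$reversible)
  expect_equal(rt$subsystem, rt2$subsystem)
  expect_equal(rt$kcat, rt2$kcat)
  expect_identical(m2$objective, m$objective)
})

test_that("GY augmentation adds exactly the three dipeptide reactions", {
  m <- toy_cho_network()
  m2 <- augment_with_gy(m)
  expect_equal(length(m2$reactions), length(m$reactions) + 3)
  expect_true(all(c("EX_glytyr(e)", "GLYTYRPEPT1t", "GLYTYRHYDRO") %in%
                  names(m2$reactions)))
  hydro <- m2$reactions[["GLYTYRHYDRO"]]$mets
  expect_equal(unname(hydro[c("gly[c]", "tyr_L[c]")]), c(1, 1))  # equimolar
  expect_equal(unname(hydro[c("h2o[c]", "glytyr[c]")]), c(-1, -1))
  expect_equal(m2$reactions[["GLYTYRHYDRO"]]$lb, 0)              # irreversible
  expect_true(m2$reactions[["EX_glytyr(e)"]]$reversible)
  expect_warning(m3 <- augment_with_gy(m2), "already")
  expect_equal(length(m3$reactions), length(m2$reactions))
})

test_that("dipeptide uptake keeps biomass producible when free Tyr is closed", {
  m <- augment_with_gy(toy_cho_network())
  m$reactions[["EX_tyr_L"]]$lb <- 0
  m$reactions[["EX_glytyr(e)"]]$lb <- -1
  s <- solve_fba(m)
  expect_gt(s$objective_value, 0.01)
  expect_gt(s$fluxes[["GLYTYRHYDRO"]], 0)
})

test_that("the antibody reaction encodes the renormalized composition", {
  r <- build_igg_reaction()
  expect_equal(unname(-r$mets[["ser_L[c]"]]), 13.25 / 100.10, tolerance = 1e-12)
  aa <- r$mets[names(r$mets) %in% unname(aa_met_ids())]
  expect_equal(sum(-aa), 1, tolerance = 1e-12)
  expect_equal(unname(r$mets[["atp[c]"]]), -4.3)
  r0 <- build_igg_reaction(energy_cost = 0)
  expect_false("atp[c]" %in% names(r0$mets))
  expect_error(build_igg_reaction(igg_composition()[-1]), "missing amino acids")
  bad <- igg_composition(); bad["ser"] <- -1
  expect_error(build_igg_reaction(bad), "negative")
})

test_that("reversible splitting counts n + r reactions and preserves optima", {
  m <- toy_cho_network()
  rt <- reaction_table(m)
  ms <- split_reversible(m)
  expect_equal(length(ms$reactions), nrow(rt) + sum(rt$reversible))
  expect_true(all(reaction_field(ms, "lb") >= 0))
  ## splitting an already irreversible model changes nothing
  m_irrev <- ms; m_irrev$split_map <- NULL
  expect_equal(length(split_reversible(m_irrev)$reactions),
               length(ms$reactions))
  ## net-flux reassembly reproduces the original optimum at steady state
  s <- solve_fba(m)
  v_net <- s$net
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% v_net[colnames(S)])), 1e-6)
  expect_equal(unname(v_net["BIOMASS_cho"]), s$objective_value,
               tolerance = 1e-8)
})

test_that("the reduced network grows, and needs glucose and a Tyr source", {
  m <- toy_cho_network()
  s <- solve_fba(m)
  expect_gt(s$objective_value, 0.05)
  expect_lt(max(abs(stoich_matrix(s$model) %*% s$fluxes)), 1e-6)
  no_glc <- m; no_glc$reactions[["EX_glc_D(e)"]]$lb <- 0
  expect_lt(solve_fba(no_glc)$objective_value, s$objective_value - 0.01)
  no_tyr <- m; no_tyr$reactions[["EX_tyr_L"]]$lb <- 0
  expect_lt(solve_fba(no_tyr)$objective_value, 1e-9)
})

test_that("no mass appears from nowhere: closed exchanges allow no growth", {
  m <- toy_cho_network(atpm = 0)
  for (id in names(m$reactions)) {
    if (startsWith(id, "EX_")) {
      m$reactions[[id]]$lb <- 0
      m$reactions[[id]]$ub <- 0
    }
  }
  s <- solve_fba(m)
  expect_lt(abs(s$objective_value), 1e-9)
  expect_lt(s$total_flux, 1e-6)   # parsimonious solution is the zero flux
})
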