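# Fold-change machinery, selection sets, intersections and the pathway /
# cofactor / partition summaries.

test_that("fold changes obey identity, floor exclusion and antisymmetry", {
  v <- c(A = 1, B = 0.5, C = 5e-5, D = 2)
  cmp_same <- fold_changes(v, v)
  expect_true(all(cmp_same$fc[cmp_same$status == "ok"] == 1))
  expect_equal(cmp_same$status[cmp_same$reaction == "C"], "excluded")

  v2 <- c(A = 1.3, B = 0.5, C = 5e-5, D = 2e-5)
  v3 <- c(A = 1.0, B = 0.5, C = 5e-5, D = 2)
  cmp <- fold_changes(v2, v3)
  expect_equal(cmp$fc[cmp$reaction == "A"], 1.3)
  expect_equal(cmp$status[cmp$reaction == "C"], "excluded")
  expect_equal(cmp$fc[cmp$reaction == "D"], 2e-5 / 2)  # one-sided floor keeps it
  ## antisymmetry on defined finite entries
  fwd <- fold_changes(v2, v3); bwd <- fold_changes(v3, v2)
  ok <- fwd$status == "ok" & bwd$status == "ok"
  expect_equal(fwd$fc[ok] * bwd$fc[ok], rep(1, sum(ok)), tolerance = 1e-12)
  ## infinite FC when only the denominator is under the floor
  v4 <- c(A = 1, B = 5e-5, C = 1, D = 1)
  v5 <- c(A = 1, B = 1, C = 5e-5, D = 1)
  cmp45 <- fold_changes(v4, v5)
  expect_equal(cmp45$status[cmp45$reaction == "C"], "infinite")
  expect_true(is.infinite(cmp45$fc[cmp45$reaction == "C"]))
  expect_error(fold_changes(c(A = 1), c(B = 1)), "different reaction sets")
})

test_that("selection is strict, includes infinities, and is monotone", {
  v_ref <- c(A = 1.2, B = 1.3, C = 1, D = 1.6, E = 1)
  v_oth <- c(A = 1.0, B = 1.0, C = 5e-5, D = 1.0, E = 1)
  cmp <- fold_changes(v_ref, v_oth)
  sel <- select_distinct(cmp, 1.2)
  expect_false("A" %in% sel)      # FC = 1.2 exactly: strict inequality
  expect_true(all(c("B", "C", "D") %in% sel))  # C infinite: included
  sel15 <- select_distinct(cmp, 1.5)
  expect_true(all(sel15 %in% sel))
  expect_true(length(sel15) <= length(sel))
})

test_that("intersection tallies respect set algebra", {
  m <- split_reversible(toy_cho_network())
  empty <- intersect_comparisons(c("G6PDH"), c("AKGD"), m)
  expect_equal(nrow(empty), 0)
  sub <- intersect_comparisons(c("G6PDH"), c("G6PDH", "AKGD", "TKT"), m)
  expect_identical(attr(sub, "reactions"), "G6PDH")
  expect_equal(sub$subsystem, "Pentose phosphate pathway")
})

test_that("summaries are invariant to zero-flux reactions and orderings", {
  m <- split_reversible(toy_cho_network())
  s <- solve_fba(toy_cho_network())
  tot <- cofactor_summary(s, cofactor = "nadph_c")
  ## production equals consumption at steady state
  cons <- 0
  for (r in s$model$reactions) {
    cf <- r$mets["nadph[c]"]
    if (!is.na(cf) && cf < 0) cons <- cons + abs(cf) * s$fluxes[[r$id]]
  }
  expect_equal(tot, unname(cons), tolerance = 1e-6)
  ## shuffling the flux vector's order changes nothing
  shuffled <- s; shuffled$fluxes <- s$fluxes[rev(names(s$fluxes))]
  expect_equal(cofactor_summary(shuffled, s$model, "nadph_c"), tot)
  expect_error(cofactor_summary(s, cofactor = "nope[c]"), "unknown cofactor")
})

test_that("doubling G6PDH flux raises the NADPH total by twice its yield", {
  s <- solve_fba(toy_cho_network())
  t0 <- cofactor_summary(s, cofactor = "nadph_c")
  s2 <- s
  s2$fluxes[["G6PDH"]] <- s$fluxes[["G6PDH"]] * 2
  t2 <- cofactor_summary(s2, cofactor = "nadph_c")
  expect_equal(t2 - t0, 2 * s$fluxes[["G6PDH"]], tolerance = 1e-9)
})

test_that("akg drain fractions are normalized shares of the transaminase set", {
  m <- split_reversible(toy_cho_network())
  v <- stats::setNames(rep(0, length(m$reactions)), names(m$reactions))
  v[c("ASPTA", "ORNTA")] <- c(2, 1)     # equal stoichiometries
  res <- akg_by_transaminases(v, m, transaminases = c("ASPTA", "ORNTA"))
  expect_equal(res$fraction, c(2 / 3, 1 / 3))
  expect_equal(sum(res$fraction), 1)
  v2 <- v; v2[c("ASPTA", "ORNTA")] <- c(1, 0)
  res2 <- akg_by_transaminases(v2, m, transaminases = c("ASPTA", "ORNTA"))
  expect_equal(res2$fraction, c(1, 0))
  expect_error(akg_by_transaminases(v, m, transaminases = "HEX1"),
               "does not involve")
})

test_that("substrate partitions close to one and respect stoichiometry", {
  m <- augment_with_gy(toy_cho_network())
  m$reactions[["EX_asn_L"]]$lb <- -0.05
  m$reactions[["EX_asn_L"]]$ub <- -0.04   # force asparagine uptake
  s <- solve_fba(m)
  part <- substrate_partition(s, substrate = "asn_L[c]",
                              sinks = c(ASNN = "ASNN"))
  expect_equal(sum(part$fraction), 1, tolerance = 1e-9)
  ## asparaginase releases equimolar ammonia: NH4 production >= ASNN flux
  nh4_prod <- 0
  for (r in s$model$reactions) {
    cf <- r$mets["nh4[c]"]
    if (!is.na(cf) && cf > 0) nh4_prod <- nh4_prod + cf * s$fluxes[[r$id]]
  }
  expect_gte(nh4_prod + 1e-9, s$fluxes[["ASNN"]])
  ## a substrate nobody consumes is flagged
  v0 <- stats::setNames(rep(0, length(s$model$reactions)),
                        names(s$model$reactions))
  expect_warning(p0 <- substrate_partition(v0, s$model, "asn_L[c]",
                                           c(ASNN = "ASNN")),
                 "fractions undefined")
  expect_true(all(is.na(p0$fraction)))
  expect_error(substrate_partition(s, substrate = "asn_L[c]",
                                   sinks = c(X = "HEX1")),
               "does not consume")
})
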