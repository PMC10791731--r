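#!/usr/bin/env Rscript
# Stage 4 — enzyme-capacity-constrained FBA on the day 6-7 phase.
#
# Converts each replicate's measured day 6-7 specific rates to
# mmol/gDCW/h, relaxes them by +/-20% as exchange bounds on the
# GY-augmented reduced CHO network, fixes the antibody flux, maximizes
# biomass with the pooled enzyme-capacity constraint and a parsimonious
# second stage, and averages replicate fluxes per condition.

suppressMessages(library(gyflux))
rates <- read.csv("results/rates.csv")
fb <- default_config()$fba

model <- augment_with_gy(toy_cho_network(p_total = fb$p_total))
model$reactions[["EX_tyr_L"]]$lb <- fb$tyr_uptake_lb
emap <- c(Glc = "EX_glc_D(e)", Lac = "EX_lac_L(e)", NH4 = "EX_nh4(e)",
          Glu = "EX_glu_L", Gln = "EX_gln_L", Asn = "EX_asn_L",
          Asp = "EX_asp_L", Ala = "EX_ala_L", GY = "EX_glytyr(e)")

for (cid in fb$conditions) {
  rc <- rates[rates$condition_id == cid & rates$phase_start == 6, ]
  reps <- split(rc, rc$batch_id)
  rate_vecs <- lapply(reps, function(rr) {
    qm <- rr$rate[match(paste0("Qm_", names(emap)), rr$variable)]
    keep <- !is.na(qm)
    setNames(per_cell_to_specific(qm[keep], fb$dcw_per_cell),
             unname(emap[keep]))
  })
  igg <- vapply(reps, function(rr)
    igg_flux_from_qp(rr$rate[rr$variable == "Qp"], fb$dcw_per_cell,
                     fb$residue_mw), numeric(1))
  sol <- condition_flux(model, rate_vecs, igg,
                        relaxation = fb$relaxation, epsilon = fb$epsilon)
  write.csv(data.frame(reaction = names(sol$fluxes),
                       flux = unname(sol$fluxes),
                       subsystem = sapply(sol$model$reactions, `[[`,
                                          "subsystem")),
            paste0("results/fluxes_", cid, ".csv"), row.names = FALSE)
  cat(cid, ": biomass", round(sol$objective_value, 4), "1/h from",
      sol$n_replicates, "replicates; G6PDH flux",
      signif(sol$fluxes[["G6PDH"]], 4), "\n")
}
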