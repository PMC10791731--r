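## Reduced CHO-like network --------------------------------------------------
##
## Desk-scale stand-in for a CHO genome-scale model, covering the pathways the
## comparative flux analysis interrogates: glycolysis, oxidative PPP entry via
## G6PDH (NADPH-producing), a full TCA cycle with AKGD and MDH
## (NADH-producing), oxidative phosphorylation, glutamate/glutamine and
## aspartate/asparagine metabolism (GLNS, GLUN, ASNN, GAD), the amino-acid
## transaminases ASPTA/ALATA/ORNTA/LEUTA draining alpha-ketoglutarate,
## anaplerosis via PCm, 4-aminobutanoate synthesis and secretion, exchanges
## for all 20 amino acids, and biomass plus IgG synthesis. Cofactor pairs
## (NAD/NADH, NADP/NADPH, FAD/FADH2, ATP/ADP/Pi) are balanced internally;
## protons are not tracked. A handful of lumped reactions (lower glycolysis,
## oxidative PPP, oxidative phosphorylation, the NADH shuttle) keep the
## network small while preserving cofactor yields; mitochondrial
## substrate-level phosphorylation draws on the single cytosolic adenylate
## pool.

toy_mets <- function() {
  cyt <- c("glc_D", "g6p", "r5p", "pyr", "lac_L", "co2", "o2", "h2o",
           "atp", "adp", "pi", "nad", "nadh", "nadp", "nadph", "nh4",
           "akg", "oaa", "glu5sa", "urea", "4abut", "4mop", "orn", "igg",
           "biomass",
           "ala_L", "arg_L", "asn_L", "asp_L", "cys_L", "gln_L", "glu_L",
           "gly", "his_L", "ile_L", "leu_L", "lys_L", "met_L", "phe_L",
           "pro_L", "ser_L", "thr_L", "trp_L", "tyr_L", "val_L")
  mit <- c("pyr", "accoa", "cit", "akg", "succoa", "succ", "fum", "mal",
           "oaa", "nad", "nadh", "fad", "fadh2", "co2", "o2", "h2o")
  ext <- c("glc_D", "lac_L", "nh4")
  df <- rbind(
    data.frame(id = paste0(ext, "[e]"), name = ext, compartment = "e"),
    data.frame(id = paste0(cyt, "[c]"), name = cyt, compartment = "c"),
    data.frame(id = paste0(mit, "[m]"), name = mit, compartment = "m"))
  df
}

#' Reduced CHO-like metabolic network
#'
#' A ~70-reaction stoichiometric network emulating the parts of CHO central
#' and amino-acid metabolism needed by the dipeptide flux analysis (see the
#' package vignette for the layout). Tyrosine enters only through its own
#' exchange or, after [augment_with_gy()], through dipeptide hydrolysis, so
#' tyrosine-source essentiality is testable. About twenty central reactions
#' carry kcat/MW annotations for the pooled enzyme-capacity constraint.
#'
#' @param p_total enzyme mass budget (g/gDCW) stored on the model
#'   (default 0.05).
#' @param atpm non-growth ATP maintenance demand, mmol/gDCW/h (lower bound
#'   of the `ATPM` reaction; default 0.3, scaled to the reduced network's
#'   exchange-flux magnitudes).
#' @return a [metabolic_model()] with objective `BIOMASS_cho`.
#' @export
toy_cho_network <- function(p_total = 0.05, atpm = 0.3) {
  aa <- aa_met_ids()            # named cytosolic AA ids
  R <- list()
  add <- function(...) reaction(...)

  ## exchanges (negative flux = uptake)
  R$`EX_glc_D(e)` <- add("EX_glc_D(e)", c("glc_D[e]" = -1), lb = -10, ub = 0,
                         subsystem = "Exchange")
  R$`EX_lac_L(e)` <- add("EX_lac_L(e)", c("lac_L[e]" = -1), lb = -5, ub = 1000,
                         subsystem = "Exchange")
  R$`EX_nh4(e)` <- add("EX_nh4(e)", c("nh4[e]" = -1), lb = -1, ub = 1000,
                       subsystem = "Exchange")
  R$EX_o2 <- add("EX_o2", c("o2[c]" = -1), lb = -1000, ub = 0, subsystem = "Exchange")
  R$EX_co2 <- add("EX_co2", c("co2[c]" = -1), lb = 0, ub = 1000, subsystem = "Exchange")
  R$EX_h2o <- add("EX_h2o", c("h2o[c]" = -1), lb = -1000, ub = 1000, subsystem = "Exchange")
  R$EX_urea <- add("EX_urea", c("urea[c]" = -1), lb = 0, ub = 1000, subsystem = "Exchange")
  R$EX_4abut <- add("EX_4abut", c("4abut[c]" = -1), lb = 0, ub = 1000, subsystem = "Exchange")
  R$EX_4mop <- add("EX_4mop", c("4mop[c]" = -1), lb = 0, ub = 1000, subsystem = "Exchange")
  R$EX_orn <- add("EX_orn", c("orn[c]" = -1), lb = -0.1, ub = 1000, subsystem = "Exchange")
  R$EX_pi <- add("EX_pi", c("pi[c]" = -1), lb = -1000, ub = 1000, subsystem = "Exchange")
  R$EX_igg <- add("EX_igg", c("igg[c]" = -1), lb = 0, ub = 1000, subsystem = "Exchange")
  R$EX_biomass <- add("EX_biomass", c("biomass[c]" = -1), lb = 0, ub = 1000,
                      subsystem = "Exchange")
  for (a in names(aa)) {
    id <- paste0("EX_", sub("\\[c\\]$", "", aa[[a]]))
    R[[id]] <- add(id, stats::setNames(-1, aa[[a]]), lb = -0.2, ub = 1000,
                   subsystem = "Exchange")
  }

  ## transport
  R$GLCt1 <- add("GLCt1", c("glc_D[e]" = -1, "glc_D[c]" = 1), lb = 0, ub = 1000,
                 subsystem = "Transport")
  R$L_LACt <- add("L_LACt", c("lac_L[c]" = -1, "lac_L[e]" = 1), lb = -1000,
                  ub = 1000, subsystem = "Transport")
  R$NH4t <- add("NH4t", c("nh4[c]" = -1, "nh4[e]" = 1), lb = -1000, ub = 1000,
                subsystem = "Transport")
  R$PYRt2m <- add("PYRt2m", c("pyr[c]" = -1, "pyr[m]" = 1), lb = 0, ub = 1000,
                  subsystem = "Transport")
  R$O2tm <- add("O2tm", c("o2[c]" = -1, "o2[m]" = 1), lb = 0, ub = 1000,
                subsystem = "Transport")
  R$CO2tm <- add("CO2tm", c("co2[m]" = -1, "co2[c]" = 1), lb = -1000, ub = 1000,
                 subsystem = "Transport")
  R$H2Otm <- add("H2Otm", c("h2o[c]" = -1, "h2o[m]" = 1), lb = -1000, ub = 1000,
                 subsystem = "Transport")
  R$AKGtm <- add("AKGtm", c("akg[c]" = -1, "akg[m]" = 1), lb = -1000, ub = 1000,
                 subsystem = "Transport")
  R$OAAtm <- add("OAAtm", c("oaa[c]" = -1, "oaa[m]" = 1), lb = -1000, ub = 1000,
                 subsystem = "Transport")
  R$NADHtm <- add("NADHtm", c("nadh[c]" = -1, "nad[m]" = -1,
                              "nad[c]" = 1, "nadh[m]" = 1),
                  lb = 0, ub = 1000, subsystem = "Transport")

  ## glycolysis / PPP (kcat 1/h, MW g/mmol)
  R$HEX1 <- add("HEX1", c("glc_D[c]" = -1, "atp[c]" = -1,
                          "g6p[c]" = 1, "adp[c]" = 1),
                subsystem = "Glycolysis/gluconeogenesis",
                kcat = 2e5, mw = 102)
  ## sugar phosphates carry one P; lumped lower glycolysis returns it in ATP
  R$GLYC <- add("GLYC", c("g6p[c]" = -1, "adp[c]" = -2, "pi[c]" = -1,
                          "nad[c]" = -2, "pyr[c]" = 2, "atp[c]" = 2,
                          "nadh[c]" = 2, "h2o[c]" = 2),
                subsystem = "Glycolysis/gluconeogenesis",
                kcat = 1.5e5, mw = 220)
  R$G6PDH <- add("G6PDH", c("g6p[c]" = -1, "nadp[c]" = -2, "h2o[c]" = -1,
                            "r5p[c]" = 1, "co2[c]" = 1, "nadph[c]" = 2),
                 subsystem = "Pentose phosphate pathway",
                 kcat = 1.2e5, mw = 59)
  R$TKT <- add("TKT", c("r5p[c]" = -6, "g6p[c]" = 5, "pi[c]" = 1),
               lb = -1000, ub = 1000,
               subsystem = "Pentose phosphate pathway",
               kcat = 9e4, mw = 68)
  R$LDH_L <- add("LDH_L", c("pyr[c]" = -1, "nadh[c]" = -1,
                            "lac_L[c]" = 1, "nad[c]" = 1),
                 lb = -1000, ub = 1000, subsystem = "Glycolysis/gluconeogenesis",
                 kcat = 3e5, mw = 35)

  ## TCA cycle and oxidative phosphorylation
  R$PDHm <- add("PDHm", c("pyr[m]" = -1, "nad[m]" = -1,
                          "accoa[m]" = 1, "nadh[m]" = 1, "co2[m]" = 1),
                subsystem = "TCA cycle", kcat = 7e4, mw = 330)
  R$CSm <- add("CSm", c("accoa[m]" = -1, "oaa[m]" = -1, "h2o[m]" = -1,
                        "cit[m]" = 1),
               subsystem = "TCA cycle", kcat = 1.6e5, mw = 98)
  R$ICDHxm <- add("ICDHxm", c("cit[m]" = -1, "nad[m]" = -1,
                              "akg[m]" = 1, "co2[m]" = 1, "nadh[m]" = 1),
                  subsystem = "TCA cycle", kcat = 1.1e5, mw = 80)
  R$AKGD <- add("AKGD", c("akg[m]" = -1, "nad[m]" = -1,
                          "succoa[m]" = 1, "co2[m]" = 1, "nadh[m]" = 1),
                subsystem = "TCA cycle", kcat = 8e4, mw = 310)
  R$SUCOASm <- add("SUCOASm", c("succoa[m]" = -1, "adp[c]" = -1, "pi[c]" = -1,
                                "succ[m]" = 1, "atp[c]" = 1),
                   subsystem = "TCA cycle", kcat = 1.3e5, mw = 75)
  R$SUCD <- add("SUCD", c("succ[m]" = -1, "fad[m]" = -1,
                          "fum[m]" = 1, "fadh2[m]" = 1),
                subsystem = "TCA cycle", kcat = 6e4, mw = 124)
  R$FUMm <- add("FUMm", c("fum[m]" = -1, "h2o[m]" = -1, "mal[m]" = 1),
                lb = -1000, ub = 1000, subsystem = "TCA cycle",
                kcat = 4e5, mw = 50)
  R$MDH <- add("MDH", c("mal[m]" = -1, "nad[m]" = -1,
                        "oaa[m]" = 1, "nadh[m]" = 1),
               lb = -1000, ub = 1000, subsystem = "TCA cycle",
               kcat = 3.3e5, mw = 36)
  R$PCm <- add("PCm", c("pyr[m]" = -1, "co2[m]" = -1, "atp[c]" = -1,
                        "oaa[m]" = 1, "adp[c]" = 1, "pi[c]" = 1),
               subsystem = "Anaplerosis", kcat = 5e4, mw = 130)
  R$NADHOXm <- add("NADHOXm", c("nadh[m]" = -1, "o2[m]" = -0.5,
                                "adp[c]" = -2.5, "pi[c]" = -2.5,
                                "nad[m]" = 1, "atp[c]" = 2.5, "h2o[c]" = 3.5),
                   subsystem = "Oxidative phosphorylation",
                   kcat = 9e4, mw = 980)
  R$FADH2OXm <- add("FADH2OXm", c("fadh2[m]" = -1, "o2[m]" = -0.5,
                                  "adp[c]" = -1.5, "pi[c]" = -1.5,
                                  "fad[m]" = 1, "atp[c]" = 1.5, "h2o[c]" = 2.5),
                    subsystem = "Oxidative phosphorylation",
                    kcat = 9e4, mw = 760)
  R$ATPM <- add("ATPM", c("atp[c]" = -1, "h2o[c]" = -1,
                          "adp[c]" = 1, "pi[c]" = 1),
                lb = atpm, ub = 1000, subsystem = "Maintenance")

  ## glutamate / glutamine / aspartate metabolism and transaminases
  R$GLUD <- add("GLUD", c("glu_L[c]" = -1, "nad[c]" = -1, "h2o[c]" = -1,
                          "akg[c]" = 1, "nh4[c]" = 1, "nadh[c]" = 1),
                lb = -1000, ub = 1000, subsystem = "Glutamate metabolism",
                kcat = 1e5, mw = 61)
  R$GLNS <- add("GLNS", c("glu_L[c]" = -1, "nh4[c]" = -1, "atp[c]" = -1,
                          "gln_L[c]" = 1, "adp[c]" = 1, "pi[c]" = 1),
                subsystem = "Glutamate metabolism", kcat = 6e4, mw = 42)
  R$GLUN <- add("GLUN", c("gln_L[c]" = -1, "h2o[c]" = -1,
                          "glu_L[c]" = 1, "nh4[c]" = 1),
                subsystem = "Glutamate metabolism")
  R$GAD <- add("GAD", c("glu_L[c]" = -1, "4abut[c]" = 1, "co2[c]" = 1),
               subsystem = "Glutamate metabolism")
  R$ASNN <- add("ASNN", c("asn_L[c]" = -1, "h2o[c]" = -1,
                          "asp_L[c]" = 1, "nh4[c]" = 1),
                subsystem = "Alanine and aspartate metabolism")
  R$ASNS <- add("ASNS", c("asp_L[c]" = -1, "gln_L[c]" = -1, "atp[c]" = -1,
                          "h2o[c]" = -1, "asn_L[c]" = 1, "glu_L[c]" = 1,
                          "adp[c]" = 1, "pi[c]" = 1),
                subsystem = "Alanine and aspartate metabolism")
  R$ASPTA <- add("ASPTA", c("asp_L[c]" = -1, "akg[c]" = -1,
                            "oaa[c]" = 1, "glu_L[c]" = 1),
                 lb = -1000, ub = 1000,
                 subsystem = "Alanine and aspartate metabolism",
                 kcat = 2e5, mw = 46)
  R$ALATA <- add("ALATA", c("ala_L[c]" = -1, "akg[c]" = -1,
                            "pyr[c]" = 1, "glu_L[c]" = 1),
                 lb = -1000, ub = 1000,
                 subsystem = "Alanine and aspartate metabolism",
                 kcat = 2e5, mw = 54)
  R$ORNTA <- add("ORNTA", c("orn[c]" = -1, "akg[c]" = -1,
                            "glu5sa[c]" = 1, "glu_L[c]" = 1),
                 subsystem = "Arginine and proline metabolism")
  R$LEUTA <- add("LEUTA", c("leu_L[c]" = -1, "akg[c]" = -1,
                            "4mop[c]" = 1, "glu_L[c]" = 1),
                 subsystem = "Valine leucine and isoleucine metabolism")
  R$P5CR <- add("P5CR", c("glu5sa[c]" = -1, "nadph[c]" = -1,
                          "pro_L[c]" = 1, "nadp[c]" = 1),
                subsystem = "Arginine and proline metabolism")
  R$ARGN <- add("ARGN", c("arg_L[c]" = -1, "h2o[c]" = -1,
                          "orn[c]" = 1, "urea[c]" = 1),
                subsystem = "Arginine and proline metabolism")

  ## biomass: amino acids (protein), g6p (carbohydrate), r5p (nucleotides),
  ## mitochondrial acetyl units (lipids), ATP and NADPH demands
  aa_coef <- c(ala = 0.60, arg = 0.25, asn = 0.25, asp = 0.30, cys = 0.10,
               gln = 0.30, glu = 0.35, gly = 0.50, his = 0.12, ile = 0.25,
               leu = 0.45, lys = 0.40, met = 0.10, phe = 0.20, pro = 0.30,
               ser = 0.35, thr = 0.30, trp = 0.06, tyr = 0.15, val = 0.30)
  bm <- stats::setNames(-aa_coef, aa[names(aa_coef)])
  bm <- c(bm, "g6p[c]" = -0.30, "r5p[c]" = -0.05, "accoa[m]" = -0.35,
          "atp[c]" = -35, "h2o[c]" = -35, "nadph[c]" = -5,
          "adp[c]" = 35, "pi[c]" = 35, "nadp[c]" = 5, "biomass[c]" = 1)
  R$BIOMASS_cho <- add("BIOMASS_cho", bm, subsystem = "Biomass")
  R$IGGSYN <- build_igg_reaction()

  metabolic_model(toy_mets(), R, objective = "BIOMASS_cho",
                  p_total = p_total, id = "toy_cho")
}
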