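## End-to-end pipeline -------------------------------------------------------
##
## Orchestrates synthetic data generation (or CSV input), specific-rate
## computation, replicate QC, batch-level PLS, condition-level ecFBA on the
## day 6-7 phase, and comparative flux analysis, writing every stage's
## tables plus a run manifest under an output directory. All numeric
## thresholds (SD band, VIP cut, bound relaxation, flux floor, fold-change
## cut, DCW conversion) are config entries, never hard-coded downstream.

#' Antibody synthesis flux from specific productivity
#'
#' Converts Qp (pg IgG/cell/day) into the residue-based synthesis flux of
#' the antibody reaction (mmol residues/gDCW/h) via the cell dry weight and
#' the mean residue mass.
#'
#' @param qp specific productivity, pg/cell/day.
#' @param dcw_per_cell cell dry weight, pg/cell (default 250).
#' @param residue_mw mean amino-acid residue mass, g/mmol (default 0.110).
#' @return flux in mmol residues/gDCW/h.
#' @export
igg_flux_from_qp <- function(qp, dcw_per_cell = 250, residue_mw = 0.110) {
  qp / dcw_per_cell / 24 / residue_mw
}

## measured-profile variables -> exchange reactions of the reduced network;
## only species with catabolic/anabolic routes in the network are bounded
exchange_map <- function() {
  c(Glc = "EX_glc_D(e)", Lac = "EX_lac_L(e)", NH4 = "EX_nh4(e)",
    Glu = "EX_glu_L", Gln = "EX_gln_L", Asn = "EX_asn_L", Asp = "EX_asp_L",
    Ala = "EX_ala_L", GY = "EX_glytyr(e)")
}

#' Default pipeline configuration
#'
#' @return nested list of pipeline parameters (see the vignette for the
#'   meaning, units and provenance of each).
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "results/run",
    synth = list(
      doses = c(0.125, 0.25, 0.5, 1, 2),
      noise_cv = 0.05,
      n_replicates = 3,
      plant_metabolite = "Glu",
      plant_sign = -1,
      plant_strength = 0.3),
    qc = list(band_k = 1, frac_threshold = 0.5),
    mvda = list(vip_threshold = 1.00, ncomp = 2),
    fba = list(
      conditions = c("GY_0.125x", "GY_0.5x", "GY_1x"),
      reference = "GY_0.5x",
      phase = c(6, 7),
      relaxation = 0.2,
      epsilon = 1e-6,
      dcw_per_cell = 250,
      residue_mw = 0.110,
      p_total = 0.05,
      tyr_uptake_lb = -0.02,
      floor = 1e-4,
      fc_threshold = 1.2))
}

check_config <- function(config, defaults = default_config()) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  for (k in names(defaults)) {
    if (is.list(defaults[[k]])) {
      if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
      else {
        bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
        if (length(bad)) stop("unknown config entries under '", k, "': ",
                              paste(bad, collapse = ", "))
        config[[k]] <- utils::modifyList(defaults[[k]], config[[k]])
      }
    } else if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  with(config, {
    stopifnot(qc$band_k > 0, qc$frac_threshold > 0, qc$frac_threshold <= 1,
              fba$relaxation >= 0, fba$floor >= 0, fba$fc_threshold > 0,
              fba$dcw_per_cell > 0, synth$noise_cv >= 0)
  })
  config
}

#' Run the full analysis pipeline
#'
#' Stages: simulate the graded-GY study (with a planted nutrient-titer
#' correlation as ground truth), compute per-phase specific rates, screen
#' replicate outliers, fit the batch-level PLS and nutrient ranking, solve
#' condition-level ecFBA on the day 6-7 phase of the dipeptide-augmented
#' network, and compare flux states against the reference condition. Every
#' stage writes CSV outputs under `config$out_dir`; a manifest records the
#' configuration and seed. Reruns with the same config are byte-identical.
#'
#' @param config configuration list (missing entries take
#'   [default_config()] values) or the path of a YAML file holding one.
#' @return invisibly, a list with every stage's in-memory results.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- check_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, ...)
  wcsv <- function(x, name) utils::write.csv(x, outfile(name), row.names = FALSE)

  ## 1. synthetic study ------------------------------------------------------
  conds <- gy_conditions(doses = config$synth$doses,
                         noise_cv = config$synth$noise_cv,
                         n_replicates = config$synth$n_replicates)
  if (!is.null(config$synth$plant_metabolite))
    conds <- plant_titer_correlation(conds, config$synth$plant_metabolite,
                                     config$synth$plant_sign,
                                     config$synth$plant_strength)
  set <- simulate_study(conds, feed_schedule(), seed = config$seed)
  wcsv(set$measurements, "measurements.csv")
  wcsv(set$feed_events, "feed_events.csv")

  ## 2. rates + 3. replicate QC ---------------------------------------------
  rates <- compute_phase_rates(set)
  wcsv(rates, "rates.csv")
  qc <- detect_outliers(set, band_k = config$qc$band_k,
                        frac_threshold = config$qc$frac_threshold)
  wcsv(qc, "qc_report.csv")
  filtered <- filter_outliers(set, qc)
  rates <- rates[!rates$batch_id %in% qc$batch_id[qc$flagged], ]

  ## 4. batch-level PLS ------------------------------------------------------
  blm <- unfold_batch_level(filtered)
  pls <- fit_pls(blm, ncomp = config$mvda$ncomp)
  ranking <- coefficient_sum_ranking(pls, blm$columns,
                                     vip_threshold = config$mvda$vip_threshold)
  wcsv(data.frame(batch_id = blm$batch_ids, condition_id = blm$condition_ids,
                  pls$T, y = blm$y), "pls_scores.csv")
  wcsv(data.frame(column = pls$columns_names, vip = unname(pls$vip),
                  coefficient = unname(pls$b)), "pls_coefficients.csv")
  wcsv(as.data.frame(ranking), "nutrient_ranking.csv")

  ## 5. condition-level ecFBA on the day 6-7 phase ---------------------------
  fb <- config$fba
  model <- augment_with_gy(toy_cho_network(p_total = fb$p_total))
  model$reactions[["EX_tyr_L"]]$lb <- fb$tyr_uptake_lb
  emap <- exchange_map()
  ph <- fb$phase
  solutions <- list()
  for (cid in fb$conditions) {
    rc <- rates[rates$condition_id == cid &
                rates$phase_start == ph[1] & rates$phase_end == ph[2], ]
    reps <- split(rc, rc$batch_id)
    rate_vecs <- lapply(reps, function(rr) {
      qm <- rr$rate[match(paste0("Qm_", names(emap)), rr$variable)]
      keep <- !is.na(qm)
      stats::setNames(per_cell_to_specific(qm[keep], fb$dcw_per_cell),
                      unname(emap[keep]))
    })
    igg <- vapply(reps, function(rr)
      igg_flux_from_qp(rr$rate[rr$variable == "Qp"], fb$dcw_per_cell,
                       fb$residue_mw), numeric(1))
    solutions[[cid]] <- condition_flux(model, rate_vecs, igg,
                                       relaxation = fb$relaxation,
                                       epsilon = fb$epsilon)
    sm <- solutions[[cid]]$model
    wcsv(data.frame(reaction = names(solutions[[cid]]$fluxes),
                    flux = unname(solutions[[cid]]$fluxes),
                    subsystem = vapply(sm$reactions, `[[`, "", "subsystem")),
         paste0("fluxes_", cid, ".csv"))
  }

  ## 6. comparative flux analysis -------------------------------------------
  ref <- solutions[[fb$reference]]
  others <- setdiff(fb$conditions, fb$reference)
  selections <- list(); comparisons <- list()
  for (cid in others) {
    cmp <- fold_changes(ref, solutions[[cid]], floor = fb$floor)
    sel <- select_distinct(cmp, fc_threshold = fb$fc_threshold)
    comparisons[[cid]] <- cmp
    selections[[cid]] <- sel
    cmp$selected <- cmp$reaction %in% sel
    wcsv(cmp, paste0("fold_changes_", fb$reference, "_vs_", cid, ".csv"))
  }
  inter <- if (length(selections) >= 2)
    intersect_comparisons(selections[[1]], selections[[2]], ref$model)
  else NULL
  if (!is.null(inter)) wcsv(inter, "repeated_reactions_by_subsystem.csv")

  cof <- do.call(rbind, lapply(names(solutions), function(cid) {
    s <- solutions[[cid]]
    data.frame(condition = cid,
               nadph_c = cofactor_summary(s, cofactor = "nadph_c"),
               nadh_m = cofactor_summary(s, cofactor = "nadh_m"),
               fadh2_m = cofactor_summary(s, cofactor = "fadh2_m"))
  }))
  wcsv(cof, "cofactor_summary.csv")
  akg <- do.call(rbind, lapply(names(solutions), function(cid)
    data.frame(condition = cid, akg_by_transaminases(solutions[[cid]]))))
  wcsv(akg, "akg_transaminases.csv")
  part <- do.call(rbind, lapply(names(solutions), function(cid) rbind(
    data.frame(condition = cid, substrate = "glu_L[c]",
               substrate_partition(solutions[[cid]], substrate = "glu_L[c]",
                                   sinks = c(GAD = "GAD", GLNS = "GLNS",
                                             IGGSYN = "IGGSYN",
                                             BIOMASS = "BIOMASS_cho"))),
    data.frame(condition = cid, substrate = "asn_L[c]",
               substrate_partition(solutions[[cid]], substrate = "asn_L[c]",
                                   sinks = c(ASNN = "ASNN"))))))
  wcsv(part, "substrate_partitions.csv")

  ## manifest (no timestamps: reruns must be byte-identical) ----------------
  manifest <- list(
    tool = "gyflux",
    version = as.character(utils::packageVersion("gyflux")),
    seed = config$seed,
    config = config,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    outputs = sort(list.files(config$out_dir)))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = config, set = set, rates = rates, qc = qc,
                 blm = blm, pls = pls, ranking = ranking,
                 solutions = solutions, comparisons = comparisons,
                 selections = selections, intersection = inter,
                 cofactors = cof, akg = akg, partitions = part))
}
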