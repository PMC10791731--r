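## Stoichiometric model container ------------------------------------------
##
## Metabolite ids carry a compartment tag in brackets ("glc_D[c]"); reaction
## ids follow BiGG-like conventions (G6PDH, AKGD, ASPTA ...) so pathway
## summaries are addressable by id. Bounds are mmol/gDCW/h.

#' Construct a stoichiometric metabolic model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (one of "e", "c", "m"); the bracketed compartment tag in `id` must match
#'   `compartment`.
#' @param reactions list of reactions as returned by [reaction()].
#' @param objective id of the objective reaction (usually biomass).
#' @param p_total optional total enzyme mass budget (g/gDCW) for the pooled
#'   enzyme-capacity constraint.
#' @param id model identifier.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = NULL,
                            p_total = NA_real_, id = "model") {
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions, objective = objective,
                      p_total = p_total),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Construct a reaction
#'
#' @param id reaction id.
#' @param mets named numeric vector of stoichiometric coefficients
#'   (negative = consumed).
#' @param lb,ub flux bounds (mmol/gDCW/h); `lb < 0` marks the reaction
#'   reversible.
#' @param subsystem pathway label.
#' @param kcat optional turnover number (1/h).
#' @param mw optional enzyme molecular weight (g/mmol).
#' @param reversible declared reversibility (default `lb < 0`); kept stable
#'   when measured-rate bounds later narrow the bound signs, so the split
#'   reaction set is identical across conditions.
#' @return reaction as a list.
#' @export
reaction <- function(id, mets, lb = 0, ub = 1000, subsystem = "",
                     kcat = NA_real_, mw = NA_real_, reversible = lb < 0) {
  if (length(mets) == 0 || all(mets == 0)) stop("reaction '", id, "' has empty stoichiometry")
  if (lb > ub) stop("reaction '", id, "': lb > ub")
  list(id = id, mets = mets[mets != 0], lb = lb, ub = ub,
       subsystem = subsystem, kcat = kcat, mw = mw, reversible = reversible)
}

validate_model <- function(model) {
  met_ids <- model$metabolites$id
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  tag <- sub("^.*\\[(.)\\]$", "\\1", met_ids)
  bad <- tag != model$metabolites$compartment
  if (any(bad)) stop("compartment tag mismatch for: ",
                     paste(met_ids[bad], collapse = ", "))
  for (r in model$reactions) {
    missing <- setdiff(names(r$mets), met_ids)
    if (length(missing))
      stop("reaction '", r$id, "' references unknown metabolites: ",
           paste(missing, collapse = ", "))
  }
  if (!is.null(model$objective) && !model$objective %in% names(model$reactions))
    stop("objective reaction '", model$objective, "' not in model")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model '", x$id, "': ", nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions", sep = "")
  if (!is.null(x$objective)) cat(", objective ", x$objective, sep = "")
  if (!is.na(x$p_total)) cat(", P_total ", x$p_total, " g/gDCW", sep = "")
  cat("\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a [metabolic_model()].
#' @return dense matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), length(model$reactions),
              dimnames = list(model$metabolites$id, names(model$reactions)))
  for (r in model$reactions) S[names(r$mets), r$id] <- r$mets
  S
}

reaction_field <- function(model, field) {
  vapply(model$reactions, function(r) r[[field]], numeric(1))
}

#' Reaction summary table
#'
#' @param model a [metabolic_model()].
#' @return data.frame with id, bounds, reversibility and subsystem per reaction.
#' @export
reaction_table <- function(model) {
  data.frame(id = names(model$reactions),
             lb = reaction_field(model, "lb"),
             ub = reaction_field(model, "ub"),
             reversible = vapply(model$reactions,
                                 function(r) isTRUE(r$reversible), TRUE),
             subsystem = vapply(model$reactions, `[[`, "", "subsystem"),
             kcat = reaction_field(model, "kcat"),
             mw = reaction_field(model, "mw"),
             row.names = NULL)
}

## IgG amino-acid composition ----------------------------------------------

#' Amino-acid composition of the produced IgG1 (mol%)
#'
#' Sequence-derived molar composition of the antibody, in mol% of residues.
#' The printed values sum to 100.10; [build_igg_reaction()] renormalises them
#' to an exact simplex so the synthesis reaction is mass-balanced.
#'
#' @return named numeric vector of mol% over the 20 proteinogenic amino acids.
#' @export
igg_composition <- function() {
  c(ser = 13.25, val = 8.89, thr = 8.28, lys = 7.38, pro = 7.23,
    leu = 6.87, gly = 6.63, ala = 5.87, glu = 4.67, tyr = 4.67,
    gln = 4.52, asn = 3.92, asp = 3.46, phe = 3.01, cys = 2.41,
    arg = 2.11, ile = 2.11, his = 1.96, trp = 1.96, met = 0.90)
}

aa_met_ids <- function() {
  c(ala = "ala_L[c]", arg = "arg_L[c]", asn = "asn_L[c]", asp = "asp_L[c]",
    cys = "cys_L[c]", gln = "gln_L[c]", glu = "glu_L[c]", gly = "gly[c]",
    his = "his_L[c]", ile = "ile_L[c]", leu = "leu_L[c]", lys = "lys_L[c]",
    met = "met_L[c]", phe = "phe_L[c]", pro = "pro_L[c]", ser = "ser_L[c]",
    thr = "thr_L[c]", trp = "trp_L[c]", tyr = "tyr_L[c]", val = "val_L[c]")
}

#' Build the antibody synthesis reaction
#'
#' Consumes free amino acids according to the antibody's molar residue
#' composition (renormalised to sum exactly 1) plus an ATP hydrolysis cost
#' per residue for peptide-bond formation and secretion, and produces one
#' unit of the `igg[c]` pseudo-metabolite. Flux unit: mmol residues/gDCW/h.
#'
#' @param composition named mol% vector over the 20 amino acids
#'   (default [igg_composition()]).
#' @param energy_cost mol ATP-equivalents hydrolysed per residue (default 4.3).
#' @return a [reaction()] with id `IGGSYN`.
#' @export
build_igg_reaction <- function(composition = igg_composition(),
                               energy_cost = 4.3) {
  ids <- aa_met_ids()
  missing <- setdiff(names(ids), names(composition))
  if (length(missing))
    stop("composition missing amino acids: ", paste(missing, collapse = ", "))
  if (any(composition < 0)) stop("negative mol% in composition")
  comp <- composition[names(ids)] / sum(composition[names(ids)])
  mets <- stats::setNames(-comp, ids[names(comp)])
  mets <- c(mets,
            "atp[c]" = -energy_cost, "h2o[c]" = -energy_cost,
            "adp[c]" = energy_cost, "pi[c]" = energy_cost,
            "igg[c]" = 1)
  reaction("IGGSYN", mets, lb = 0, ub = 1000, subsystem = "Protein production")
}

## GY dipeptide augmentation -----------------------------------------------

#' Add glycyl-L-tyrosine dipeptide reactions to a model
#'
#' Adds GY uptake (`EX_glytyr(e)`), PepT1-type transport (`GLYTYRPEPT1t`)
#' and intracellular hydrolysis (`GLYTYRHYDRO`: h2o[c] + glytyr[c] ->
#' gly[c] + tyr_L[c]) so the dipeptide can serve as a tyrosine (and glycine)
#' source. Exchange and transport are reversible, hydrolysis irreversible.
#' Re-augmenting an already augmented model is a no-op with a warning.
#'
#' @param model a [metabolic_model()] containing `gly[c]`, `tyr_L[c]` and
#'   `h2o[c]`.
#' @return augmented model.
#' @export
augment_with_gy <- function(model) {
  if ("GLYTYRHYDRO" %in% names(model$reactions)) {
    warning("model already carries GY reactions; augmentation skipped")
    return(model)
  }
  need <- c("gly[c]", "tyr_L[c]", "h2o[c]")
  missing <- setdiff(need, model$metabolites$id)
  if (length(missing))
    stop("cannot augment: model lacks ", paste(missing, collapse = ", "))
  model$metabolites <- rbind(model$metabolites,
    data.frame(id = c("glytyr[e]", "glytyr[c]"),
               name = c("glycyl-L-tyrosine", "glycyl-L-tyrosine"),
               compartment = c("e", "c")))
  add <- list(
    reaction("EX_glytyr(e)", c("glytyr[e]" = -1), lb = -1000, ub = 1000,
             subsystem = "Exchange"),
    reaction("GLYTYRPEPT1t", c("glytyr[e]" = -1, "glytyr[c]" = 1),
             lb = -1000, ub = 1000, subsystem = "Transport"),
    reaction("GLYTYRHYDRO",
             c("h2o[c]" = -1, "glytyr[c]" = -1, "gly[c]" = 1, "tyr_L[c]" = 1),
             lb = 0, ub = 1000, subsystem = "Dipeptide metabolism"))
  names(add) <- vapply(add, `[[`, "", "id")
  model$reactions <- c(model$reactions, add)
  validate_model(model)
}

## Reversible splitting ------------------------------------------------------

#' Split reversible reactions into forward/backward pairs
#'
#' Each reaction declared reversible is replaced by a forward copy (bounds
#' `[max(0, lb), max(0, ub)]`) and a backward copy with negated stoichiometry
#' (bounds `[max(0, -ub), max(0, -lb)]`), so all fluxes are non-negative and
#' the split reaction set does not depend on the signs measured-rate bounds
#' happen to take. A mapping to reassemble net fluxes is attached as
#' `model$split_map`.
#'
#' @param model a [metabolic_model()].
#' @return model with only irreversible reactions.
#' @export
split_reversible <- function(model) {
  out <- list()
  map <- list()
  for (r in model$reactions) {
    rev_flag <- if (is.null(r$reversible)) r$lb < 0 else r$reversible
    if (rev_flag) {
      fwd <- r; fwd$lb <- max(0, r$lb); fwd$ub <- max(0, r$ub)
      fwd$reversible <- FALSE
      bwd <- r; bwd$id <- paste0(r$id, "_rev"); bwd$mets <- -r$mets
      bwd$lb <- max(0, -r$ub); bwd$ub <- max(0, -r$lb)
      bwd$reversible <- FALSE
      out[[fwd$id]] <- fwd; out[[bwd$id]] <- bwd
      map[[r$id]] <- c(fwd = fwd$id, rev = bwd$id)
    } else {
      out[[r$id]] <- r
      map[[r$id]] <- c(fwd = r$id, rev = NA_character_)
    }
  }
  model$reactions <- out
  model$split_map <- map
  model
}

#' Reassemble net fluxes from a split model's flux vector
#'
#' @param fluxes named flux vector over a split model's reactions.
#' @param model the split model (with `split_map`).
#' @return named net flux vector over the original reaction ids.
#' @export
net_fluxes <- function(fluxes, model) {
  if (is.null(model$split_map)) stop("model has no split_map; call split_reversible() first")
  vapply(model$split_map, function(m) {
    v <- fluxes[[m[["fwd"]]]]
    if (!is.na(m[["rev"]])) v <- v - fluxes[[m[["rev"]]]]
    v
  }, numeric(1))
}

## JSON input/output ---------------------------------------------------------

#' Read a metabolic model from JSON or SBML
#'
#' Format is auto-detected from the file extension (`.json` vs
#' `.xml`/`.sbml`).
#'
#' @param path file path.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = read_model_json(path),
         xml = ,
         sbml = read_sbml(path),
         stop("unrecognised model format: .", ext))
}

#' Write a metabolic model to JSON
#'
#' Cobra-like JSON dialect: `metabolites` (id, name, compartment),
#' `reactions` (id, metabolites map, lower_bound, upper_bound, subsystem,
#' kcat, mw), `objective`, `p_total`.
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    id = model$id,
    metabolites = model$metabolites,
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id, metabolites = as.list(r$mets),
           lower_bound = r$lb, upper_bound = r$ub,
           reversible = isTRUE(r$reversible),
           subsystem = r$subsystem, kcat = r$kcat, mw = r$mw)
    }),
    objective = model$objective,
    p_total = model$p_total)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, name = m$name, compartment = m$compartment)))
  rxns <- lapply(obj$reactions, function(r) {
    reaction(r$id, unlist(r$metabolites),
             lb = r$lower_bound, ub = r$upper_bound,
             subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
             kcat = if (is.null(r$kcat)) NA_real_ else r$kcat,
             mw = if (is.null(r$mw)) NA_real_ else r$mw,
             reversible = if (is.null(r$reversible)) r$lower_bound < 0
                          else isTRUE(r$reversible))
  })
  metabolic_model(mets, rxns,
                  objective = obj$objective,
                  p_total = if (is.null(obj$p_total)) NA_real_ else obj$p_total,
                  id = if (is.null(obj$id)) "model" else obj$id)
}

## SBML input/output ---------------------------------------------------------
##
## Minimal SBML Level 3 + FBC v2 writer/reader scoped to this container:
## compartments, species, reactions with stoichiometry, flux bounds via
## parameters, an objective, and subsystem/kcat/MW carried in reaction notes.
## Original (bracketed) ids are kept in the `name` attributes; SBML ids are
## sanitised BiGG-style (M_glc_D_c, R_EX_glc_D_e).

sbml_sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Write a metabolic model to SBML (Level 3, FBC)
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @export
write_sbml <- function(model, path) {
  ns_sbml <- "http://www.sbml.org/sbml/level3/version1/core"
  ns_fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root("sbml", xmlns = ns_sbml, "xmlns:fbc" = ns_fbc,
                            level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_sanitize(model$id),
                             "fbc:strict" = "true")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in unique(model$metabolites$compartment))
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  met_sid <- stats::setNames(
    paste0("M_", sbml_sanitize(sub("\\[(.)\\]$", "_\\1", model$metabolites$id))),
    model$metabolites$id)
  for (i in seq_len(nrow(model$metabolites)))
    xml2::xml_add_child(sp, "species",
                        id = met_sid[[model$metabolites$id[i]]],
                        name = model$metabolites$id[i],
                        compartment = model$metabolites$compartment[i],
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  ## one parameter per distinct bound value
  num17 <- function(x) sprintf("%.17g", x)
  bounds <- sort(unique(c(reaction_field(model, "lb"),
                          reaction_field(model, "ub"))))
  par_id <- stats::setNames(paste0("bnd_", seq_along(bounds)), num17(bounds))
  pl <- xml2::xml_add_child(mdl, "listOfParameters")
  for (b in bounds)
    xml2::xml_add_child(pl, "parameter", id = par_id[[num17(b)]],
                        value = num17(b), constant = "true")
  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(rl, "reaction",
      id = paste0("R_", sbml_sanitize(r$id)), name = r$id,
      reversible = if (isTRUE(r$reversible)) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = par_id[[num17(r$lb)]],
      "fbc:upperFluxBound" = par_id[[num17(r$ub)]])
    notes <- xml2::xml_add_child(rn, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    if (!is.na(r$kcat)) xml2::xml_add_child(body, "p", paste0("KCAT: ", num17(r$kcat)))
    if (!is.na(r$mw)) xml2::xml_add_child(body, "p", paste0("MW: ", num17(r$mw)))
    subs <- r$mets[r$mets < 0]; prods <- r$mets[r$mets > 0]
    if (length(subs)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(subs))
        xml2::xml_add_child(lr, "speciesReference", species = met_sid[[m]],
                            stoichiometry = num17(-subs[[m]]),
                            constant = "true")
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prods))
        xml2::xml_add_child(lp, "speciesReference", species = met_sid[[m]],
                            stoichiometry = num17(prods[[m]]),
                            constant = "true")
    }
  }
  if (!is.null(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sbml_sanitize(model$objective)),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a metabolic model from SBML (Level 3, FBC)
#'
#' @param path SBML file as written by [write_sbml()] or a compatible
#'   exporter using FBC flux-bound parameters.
#' @return a [metabolic_model()].
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (is.na(mdl)) stop("no <model> element in ", path)

  sp_nodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  sid <- xml2::xml_attr(sp_nodes, "id")
  sname <- xml2::xml_attr(sp_nodes, "name")
  scomp <- xml2::xml_attr(sp_nodes, "compartment")
  orig <- ifelse(is.na(sname) | sname == "",
                 paste0(sub("_(.)$", "", sub("^M_", "", sid)), "[", scomp, "]"),
                 sname)
  mets <- data.frame(id = orig, name = orig, compartment = scomp)
  sid2orig <- stats::setNames(orig, sid)

  par_nodes <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  note_field <- function(rn, key) {
    ps <- xml2::xml_text(xml2::xml_find_all(rn, ".//notes//p"))
    hit <- grep(paste0("^", key, ": "), ps, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", key, ": "), "", hit[[1]])
  }
  rxns <- lapply(xml2::xml_find_all(mdl, ".//listOfReactions/reaction"), function(rn) {
    rid <- xml2::xml_attr(rn, "name")
    if (is.na(rid) || rid == "") rid <- sub("^R_", "", xml2::xml_attr(rn, "id"))
    coef <- function(xpath, sign) {
      refs <- xml2::xml_find_all(rn, xpath)
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      sid2orig[xml2::xml_attr(refs, "species")])
    }
    mets_r <- c(coef(".//listOfReactants/speciesReference", -1),
                coef(".//listOfProducts/speciesReference", 1))
    lb <- par_val[[xml2::xml_attr(rn, "lowerFluxBound")]]
    ub <- par_val[[xml2::xml_attr(rn, "upperFluxBound")]]
    sub_lab <- note_field(rn, "SUBSYSTEM")
    kcat <- suppressWarnings(as.numeric(note_field(rn, "KCAT")))
    mw <- suppressWarnings(as.numeric(note_field(rn, "MW")))
    reaction(rid, mets_r, lb = lb, ub = ub,
             subsystem = if (is.na(sub_lab)) "" else sub_lab,
             kcat = kcat, mw = mw,
             reversible = identical(xml2::xml_attr(rn, "reversible"), "true"))
  })
  obj_node <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  objective <- NULL
  if (!is.na(obj_node)) {
    oid <- sub("^R_", "", xml2::xml_attr(obj_node, "reaction"))
    rids <- vapply(rxns, `[[`, "", "id")
    objective <- rids[sbml_sanitize(rids) == oid][1]
  }
  metabolic_model(mets, rxns, objective = objective,
                  id = xml2::xml_attr(mdl, "id"))
}
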