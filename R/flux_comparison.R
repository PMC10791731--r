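## Comparative flux analysis -------------------------------------------------
##
## Compares condition-level flux states against the reference condition via
## fold changes over the split (irreversible) reaction set, selects
## distinctly up-shifted reactions, intersects selections across
## comparisons, and summarises cofactor generation, alpha-ketoglutarate
## drain by transaminases and substrate partitioning.

as_flux_vector <- function(x) {
  if (inherits(x, "flux_solution")) x$fluxes else x
}

#' Reaction-wise flux fold changes between two conditions
#'
#' `FC = v_ref / v_other` per irreversible reaction; the reference condition
#' sits in the numerator, so "FC > threshold" reads "flux higher in the
#' reference". Reactions with both fluxes below the floor are excluded;
#' a below-floor denominator with an above-floor numerator yields an
#' infinite FC, kept and flagged.
#'
#' @param v_ref,v_other named flux vectors over the same split reaction set
#'   (or `flux_solution` objects).
#' @param floor flux floor, mmol/gDCW/h (default 0.0001).
#' @return data.frame (class `flux_comparison`): reaction, v_ref, v_other,
#'   fc, status (`"ok"`, `"infinite"`, `"excluded"`).
#' @export
fold_changes <- function(v_ref, v_other, floor = 1e-4) {
  v_ref <- as_flux_vector(v_ref); v_other <- as_flux_vector(v_other)
  if (!identical(sort(names(v_ref)), sort(names(v_other))))
    stop("flux vectors cover different reaction sets")
  v_other <- v_other[names(v_ref)]
  both_low <- v_ref < floor & v_other < floor
  inf_fc <- v_other < floor & v_ref >= floor
  fc <- ifelse(both_low, NA_real_,
               ifelse(inf_fc, Inf, v_ref / v_other))
  status <- ifelse(both_low, "excluded", ifelse(inf_fc, "infinite", "ok"))
  structure(data.frame(reaction = names(v_ref), v_ref = unname(v_ref),
                       v_other = unname(v_other), fc = unname(fc),
                       status = status, row.names = NULL),
            class = c("flux_comparison", "data.frame"),
            floor = floor)
}

#' Select distinctly up-shifted reactions
#'
#' Strict inequality `FC > fc_threshold`; infinite fold changes are
#' included.
#'
#' @param cmp a `flux_comparison`.
#' @param fc_threshold fold-change cut (default 1.2).
#' @return character vector of reaction ids.
#' @export
select_distinct <- function(cmp, fc_threshold = 1.2) {
  ok <- cmp$status != "excluded" & !is.na(cmp$fc) & cmp$fc > fc_threshold
  cmp$reaction[ok]
}

#' Reactions recurring in two comparison selections, by subsystem
#'
#' @param setA,setB reaction-id vectors from [select_distinct()].
#' @param model the (split) model supplying subsystem labels.
#' @return data.frame subsystem/n sorted descending, with the intersected
#'   reaction ids as attribute `reactions`.
#' @export
intersect_comparisons <- function(setA, setB, model) {
  common <- intersect(setA, setB)
  if (!length(common)) {
    tab <- data.frame(subsystem = character(), n = integer())
    attr(tab, "reactions") <- character()
    return(tab)
  }
  subs <- vapply(common, function(r) model$reactions[[r]]$subsystem, "")
  tab <- as.data.frame(table(subsystem = subs), stringsAsFactors = FALSE)
  names(tab)[2] <- "n"
  tab <- tab[order(-tab$n, tab$subsystem), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "reactions") <- common
  tab
}

#' Aliases for the summarised redox cofactors
#' @return named vector mapping summary keys to metabolite ids.
#' @export
cofactor_ids <- function() {
  c(nadph_c = "nadph[c]", nadh_m = "nadh[m]", fadh2_m = "fadh2[m]")
}

#' Total flux generating a redox cofactor
#'
#' Sums `coefficient x flux` over all split reactions producing the
#' cofactor (positive stoichiometric coefficient), i.e. the total reduction
#' flux of that cofactor pool.
#'
#' @param solution a `flux_solution` (or named split flux vector with
#'   `model` supplied).
#' @param model split model (defaults to `solution$model`).
#' @param cofactor summary key (`"nadph_c"`, `"nadh_m"`, `"fadh2_m"`) or a
#'   metabolite id.
#' @return total producing flux, mmol/gDCW/h.
#' @export
cofactor_summary <- function(solution, model = NULL,
                             cofactor = c("nadph_c", "nadh_m", "fadh2_m")) {
  if (is.null(model)) model <- solution$model
  if (length(cofactor) > 1) cofactor <- cofactor[1]
  met <- if (cofactor %in% names(cofactor_ids())) cofactor_ids()[[cofactor]]
         else cofactor
  if (!met %in% model$metabolites$id) stop("unknown cofactor: ", cofactor)
  v <- as_flux_vector(solution)
  tot <- 0
  for (r in model$reactions) {
    cf <- unname(r$mets[met])
    if (!is.na(cf) && cf > 0) tot <- tot + cf * v[[r$id]]
  }
  unname(tot)
}

#' Alpha-ketoglutarate drain by amino-acid transaminases
#'
#' Per-reaction akg consumption (`|stoichiometry| x flux`) and each
#' transaminase's share of the total transaminase drain.
#'
#' @param solution a `flux_solution`.
#' @param model split model (defaults to `solution$model`).
#' @param transaminases reaction ids of the transaminase set.
#' @param akg_id alpha-ketoglutarate metabolite id.
#' @return data.frame reaction/akg_drain/fraction.
#' @export
akg_by_transaminases <- function(solution, model = NULL,
                                 transaminases = c("ASPTA", "ALATA",
                                                   "ORNTA", "LEUTA"),
                                 akg_id = "akg[c]") {
  if (is.null(model)) model <- solution$model
  v <- as_flux_vector(solution)
  drain <- vapply(transaminases, function(id) {
    ids <- intersect(c(id, paste0(id, "_rev")), names(model$reactions))
    if (!length(ids)) stop("reaction not in model: ", id)
    d <- 0
    for (rid in ids) {
      cf <- model$reactions[[rid]]$mets[akg_id]
      if (is.na(cf)) stop("reaction ", id, " does not involve ", akg_id)
      if (cf < 0) d <- d + abs(cf) * v[[rid]]
    }
    d
  }, numeric(1))
  tot <- sum(drain)
  data.frame(reaction = transaminases, akg_drain = unname(drain),
             fraction = if (tot > 0) unname(drain) / tot else NA_real_,
             row.names = NULL)
}

#' Partition of a substrate's consumption over sink reactions
#'
#' Total available substrate = the summed consumption flux over all split
#' reactions consuming it; each named sink's share is its drain divided by
#' that total, with the remainder reported as `other/secreted`.
#'
#' @param solution a `flux_solution`.
#' @param model split model (defaults to `solution$model`).
#' @param substrate metabolite id (e.g. `"glu_L[c]"`).
#' @param sinks named sink reaction ids.
#' @return data.frame sink/drain/fraction including the remainder row;
#'   zero total consumption yields NA fractions with a warning.
#' @export
substrate_partition <- function(solution, model = NULL, substrate, sinks) {
  if (is.null(model)) model <- solution$model
  v <- as_flux_vector(solution)
  if (!substrate %in% model$metabolites$id) stop("unknown substrate: ", substrate)
  consumption <- function(rid) {
    cf <- model$reactions[[rid]]$mets[substrate]
    if (is.na(cf) || cf >= 0) 0 else abs(cf) * v[[rid]]
  }
  total <- sum(vapply(names(model$reactions), consumption, numeric(1)))
  drain <- vapply(sinks, function(id) {
    ids <- intersect(c(id, paste0(id, "_rev")), names(model$reactions))
    if (!length(ids)) stop("sink not in model: ", id)
    if (all(vapply(ids, function(rid)
      is.na(model$reactions[[rid]]$mets[substrate]), TRUE)))
      stop("sink ", id, " does not consume ", substrate)
    sum(vapply(ids, consumption, numeric(1)))
  }, numeric(1))
  if (total <= 0) {
    warning("no consumption of ", substrate, "; fractions undefined")
    frac <- rep(NA_real_, length(sinks) + 1)
  } else {
    frac <- c(drain / total, (total - sum(drain)) / total)
  }
  data.frame(sink = c(sinks, "other/secreted"),
             drain = c(unname(drain), max(0, total - sum(drain))),
             fraction = unname(frac), row.names = NULL)
}
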