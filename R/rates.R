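## Specific-rate computation -------------------------------------------------
##
## Transforms culture profiles into per-phase specific rates: integrated
## viable cell density (IVCD, trapezoidal), specific growth rate (SGR),
## specific productivity (Qp) and specific metabolite consumption/production
## rates (Qm), with feed correction for bolus events. Units: VCD in 10^6
## cells/mL, concentrations in mM (1 mM = 10^6 pmol/mL), titer in mg/L
## (1 mg/L = 10^6 pg/mL), so Qm and Qp come out in pmol/cell/day and
## pg/cell/day without explicit conversion factors.

#' The culture phases used for rate computation
#'
#' Consecutive sampling-day intervals (half-open `[t1, t2)`).
#'
#' @return two-column matrix of phase start/end days.
#' @export
default_phases <- function() {
  s <- SAMPLING_DAYS
  cbind(start = s[-length(s)], end = s[-1])
}

#' Integrated viable cell density over an interval (trapezoidal)
#'
#' @param vcd1,vcd2 viable cell density at the endpoints (10^6 cells/mL).
#' @param t1,t2 interval endpoints (days), `t2 > t1`.
#' @return IVCD, 10^6 cell.day/mL.
#' @export
integrate_vcd <- function(vcd1, vcd2, t1, t2) {
  if (any(t2 <= t1)) stop("t2 must be greater than t1")
  if (any(vcd1 < 0 | vcd2 < 0)) stop("VCD must be non-negative")
  (vcd1 + vcd2) / 2 * (t2 - t1)
}

#' Specific metabolite consumption/production rate
#'
#' `Qm = (C2 - (C1 + C_feed)) / IVCD`; negative = net consumption.
#'
#' @param c1,c2 concentrations at phase start/end (mM).
#' @param c_feed concentration increase contributed by feed additions during
#'   the phase (mM).
#' @param ivcd integrated viable cell density (10^6 cell.day/mL).
#' @return Qm, pmol/cell/day.
#' @export
specific_rate <- function(c1, c2, c_feed, ivcd) {
  if (any(ivcd <= 0)) stop("IVCD must be positive for a specific rate")
  (c2 - (c1 + c_feed)) / ivcd
}

#' Specific product (IgG) formation rate
#'
#' `Qp = (Cp2 - Cp1) / IVCD`.
#'
#' @param cp1,cp2 titer at phase start/end (mg/L).
#' @param ivcd integrated viable cell density (10^6 cell.day/mL).
#' @return Qp, pg/cell/day.
#' @export
specific_productivity <- function(cp1, cp2, ivcd) {
  if (any(ivcd <= 0)) stop("IVCD must be positive for a specific rate")
  (cp2 - cp1) / ivcd
}

#' Specific growth rate over an interval
#'
#' Exponential-phase definition `ln(vcd2/vcd1)/(t2 - t1)`.
#'
#' @param vcd1,vcd2 viable cell densities (positive).
#' @param t1,t2 interval endpoints (days).
#' @return SGR, 1/day.
#' @export
growth_rate <- function(vcd1, vcd2, t1, t2) {
  if (any(t2 <= t1)) stop("t2 must be greater than t1")
  if (any(vcd1 <= 0 | vcd2 <= 0)) stop("VCD must be positive for SGR")
  log(vcd2 / vcd1) / (t2 - t1)
}

#' Feed-contributed concentration increase at a bolus event
#'
#' A bolus of volume fraction `f` with feedstock concentration `C` raises
#' the culture concentration by `f*C/(1+f)` (the residual is simultaneously
#' diluted by `1/(1+f)`, which is handled as a separate correction).
#'
#' @param schedule a [feed_schedule()].
#' @param day bolus day (must be in the schedule).
#' @return named vector of concentration increases (mM).
#' @export
feed_delta <- function(schedule, day) {
  if (!day %in% schedule$bolus_days)
    return(stats::setNames(numeric(0), character(0)))
  f <- schedule$bolus_fraction
  schedule$feed_composition * f / (1 + f)
}

#' Per-phase specific rates for every batch of a culture set
#'
#' Applies the trapezoidal IVCD, SGR, Qp and Qm definitions per phase with
#' feed correction from the recorded feed events. By default the bolus
#' dilution of residual concentration, titer and cells (factor `1/(1+f)`)
#' is corrected in addition to the feed mass term; `eq2_strict = TRUE`
#' restricts the correction to the additive feed term only (the literal
#' rate-equation reading, which ignores the ~4% volume step).
#'
#' @param set a `culture_set` (see [simulate_fedbatch()]).
#' @param phases two-column matrix of phase boundaries
#'   (default [default_phases()]); endpoints must be sampled days.
#' @param eq2_strict disable the residual-dilution correction.
#' @return data.frame: batch_id, condition_id, phase_start, phase_end,
#'   variable (`IVCD`, `SGR`, `Qp`, or `Qm_<metabolite>`), rate, units.
#' @export
compute_phase_rates <- function(set, phases = default_phases(),
                                eq2_strict = FALSE) {
  m <- set$measurements
  out <- list()
  for (bid in unique(m$batch_id)) {
    mb <- m[m$batch_id == bid, ]
    cid <- mb$condition_id[1]
    ev <- set$feed_events[set$feed_events$batch_id == bid, , drop = FALSE]
    val <- function(variable, day) {
      v <- mb$value[mb$variable == variable & mb$day == day]
      if (!length(v))
        stop("batch ", bid, ": no '", variable, "' measurement on day ", day)
      v[1]
    }
    mets <- setdiff(unique(mb$variable), c("VCD", "viability", "titer"))
    for (i in seq_len(nrow(phases))) {
      t1 <- phases[i, 1]; t2 <- phases[i, 2]
      for (d in c(t1, t2))
        if (!d %in% mb$day)
          stop("batch ", bid, ": phase ", t1, "-", t2,
               " endpoint day ", d, " was not sampled")
      in_phase <- ev[ev$day >= t1 & ev$day < t2, , drop = FALSE]
      f1 <- if (nrow(in_phase)) max(0, in_phase$bolus_fraction[in_phase$day == t1][1], na.rm = TRUE) else 0
      if (is.na(f1) || !length(f1)) f1 <- 0
      dil <- if (eq2_strict) 1 else 1 + f1
      vcd1 <- val("VCD", t1) / dil
      vcd2 <- val("VCD", t2)
      ivcd <- integrate_vcd(vcd1, vcd2, t1, t2)
      sgr <- growth_rate(vcd1, vcd2, t1, t2)
      qp <- specific_productivity(val("titer", t1) / dil, val("titer", t2), ivcd)
      if (qp < 0)
        message("batch ", bid, ": negative Qp in phase ", t1, "-", t2)
      rows <- data.frame(
        variable = c("IVCD", "SGR", "Qp"),
        rate = c(ivcd, sgr, qp),
        units = c("1e6 cell.day/mL", "1/day", "pg/cell/day"))
      for (met in mets) {
        cf <- if (nrow(in_phase))
          sum(in_phase$added_conc[in_phase$metabolite == met]) else 0
        qm <- specific_rate(val(met, t1) / dil, val(met, t2), cf, ivcd)
        rows <- rbind(rows, data.frame(variable = paste0("Qm_", met),
                                       rate = qm, units = "pmol/cell/day"))
      }
      rows <- data.frame(batch_id = bid, condition_id = cid,
                         phase_start = t1, phase_end = t2, rows,
                         row.names = NULL)
      out[[length(out) + 1]] <- rows
    }
  }
  do.call(rbind, out)
}
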