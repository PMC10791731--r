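## Synthetic fed-batch culture generator -------------------------------------
##
## Emulates the statistical and temporal structure of an IgG-producing CHO
## fed-batch study with graded glycyl-L-tyrosine (GY) dipeptide feed doses:
## 14-day cultures sampled on days 0,2,4,5,6,7,8,10,12,14 with daily VCD,
## 4% v/v feed boluses every second day from day 4, glucose setpoint top-ups,
## a unimodal dose-response peaking at the 0.5x GY dose, replicates that
## differ only by multiplicative lognormal measurement noise, and hooks to
## plant outlier batches and nutrient-titer correlations for ground-truth
## testing.
##
## Measured concentrations update between consecutive sampling days through
## the same trapezoidal cell-density integral the rate equations use, so
## planted specific rates are exactly recoverable at zero noise.

SAMPLING_DAYS <- c(0, 2, 4, 5, 6, 7, 8, 10, 12, 14)

#' Fed-batch feed schedule
#'
#' @param bolus_days days on which a feed bolus is applied.
#' @param bolus_fraction bolus volume as a fraction of current culture
#'   volume (v/v).
#' @param feed_composition named vector, feedstock concentration per
#'   metabolite (mM).
#' @param glucose_setpoints data.frame `from`/`to`/`target_g_l`: after each
#'   bolus in `[from, to]`, glucose is topped up to the target (g/L);
#'   ranges must not overlap.
#' @return object of class `feed_schedule`.
#' @export
feed_schedule <- function(bolus_days = c(4, 6, 8, 10, 12),
                          bolus_fraction = 0.04,
                          feed_composition = default_feed_composition(),
                          glucose_setpoints = data.frame(
                            from = c(4, 9), to = c(8, 12),
                            target_g_l = c(6, 7))) {
  if (bolus_fraction <= 0 || bolus_fraction >= 1)
    stop("bolus_fraction must be in (0, 1)")
  gs <- glucose_setpoints[order(glucose_setpoints$from), , drop = FALSE]
  if (nrow(gs) > 1 && any(gs$from[-1] <= gs$to[-nrow(gs)]))
    stop("glucose setpoint ranges overlap")
  structure(list(bolus_days = bolus_days, bolus_fraction = bolus_fraction,
                 feed_composition = feed_composition,
                 glucose_setpoints = gs),
            class = "feed_schedule")
}

#' Default concentrated feed composition (mM)
#'
#' Tyrosine is supplied only as the GY dipeptide (scaled by the condition's
#' dose); glutamine is basal-medium only, matching common CHO feed designs.
#'
#' @return named numeric vector of feedstock concentrations.
#' @export
default_feed_composition <- function() {
  c(Asn = 100, Asp = 30, Ala = 0, Arg = 40, Cys = 15, Gln = 0, Glu = 20,
    Gly = 20, His = 20, Ile = 40, Leu = 60, Lys = 45, Met = 20, Phe = 30,
    Pro = 40, Ser = 50, Thr = 40, Trp = 15, Tyr = 0, Val = 45, GY = 40)
}

GLUCOSE_MW <- 180.16  # g/mol; g/L -> mM conversion at ingest

#' Convert glucose g/L to mM
#' @param g_l concentration in g/L.
#' @return concentration in mM.
#' @export
glucose_g_l_to_mm <- function(g_l) g_l / GLUCOSE_MW * 1000

## dose-response factor: unimodal in log-dose, peaking at the 0.5x GY dose
gy_dose_factor <- function(gy_dose, sigma = 1.1) {
  exp(-(log2(gy_dose / 0.5))^2 / (2 * sigma^2))
}

#' Specification of one culture condition
#'
#' Growth, productivity and peak density are unimodal in the GY dose via a
#' log-normal-shaped dose factor peaking at 0.5x; per-metabolite base rates
#' are held constant over the culture so they are exactly recoverable.
#'
#' @param condition_id label, e.g. `"GY_0.5x"`.
#' @param gy_dose GY dose multiplier (1 = the reference feed's Tyr molarity).
#' @param mu_max maximum specific growth rate at the optimal dose (1/day).
#' @param decline_rate first-order death rate after the peak (1/day).
#' @param qp_max peak specific productivity at the optimal dose (pg/cell/day).
#' @param base_rates named vector of specific rates (pmol/cell/day; negative
#'   = consumption), names matching the simulated metabolites.
#' @param noise_cv multiplicative lognormal measurement noise CV.
#' @param n_replicates replicate bioreactors.
#' @param inoculation_density starting VCD (10^6 cells/mL).
#' @param volume_ml initial working volume.
#' @param x_max carrying capacity of the logistic growth phase at the optimal
#'   dose (10^6 cells/mL).
#' @param peak_day day growth switches to decline.
#' @param planted_mu optional named per-phase growth rates (1/day), names
#'   `"t1-t2"` over the sampling phases; overrides the logistic model with
#'   piecewise-exponential growth (used for rate round-trip testing).
#' @param planted list of planted nutrient-titer correlations (see
#'   [plant_titer_correlation()]).
#' @return object of class `condition_spec`.
#' @export
condition_spec <- function(condition_id, gy_dose = 0.5, mu_max = 0.62,
                           decline_rate = 0.12, qp_max = 24,
                           base_rates = default_base_rates(),
                           noise_cv = 0.05, n_replicates = 3,
                           inoculation_density = 0.3, volume_ml = 12,
                           x_max = 42, peak_day = 8,
                           planted_mu = NULL, planted = list()) {
  if (mu_max <= 0) stop("mu_max must be positive")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(condition_id = condition_id, gy_dose = gy_dose,
                 mu_max = mu_max, decline_rate = decline_rate,
                 qp_max = qp_max, base_rates = base_rates,
                 noise_cv = noise_cv, n_replicates = n_replicates,
                 inoculation_density = inoculation_density,
                 volume_ml = volume_ml, x_max = x_max, peak_day = peak_day,
                 planted_mu = planted_mu, planted = planted),
            class = "condition_spec")
}

#' Default specific rates of the simulated metabolites (pmol/cell/day)
#'
#' Negative = net consumption. Glucose consumption is scaled so the
#' two-day bolus/top-up schedule keeps residual glucose positive.
#'
#' @return named numeric vector.
#' @export
default_base_rates <- function() {
  c(Glc = -0.9, Lac = 0.55, NH4 = 0.22,
    Ala = 0.10, Arg = -0.035, Asn = -0.08, Asp = -0.03, Cys = -0.015,
    Gln = -0.12, Glu = 0.02, Gly = -0.02, His = -0.02, Ile = -0.04,
    Leu = -0.06, Lys = -0.045, Met = -0.02, Phe = -0.03, Pro = -0.035,
    Ser = -0.05, Thr = -0.04, Trp = -0.012, Tyr = -0.035, Val = -0.045)
}

#' Default initial medium concentrations (mM)
#' @return named numeric vector.
#' @export
default_initial_conc <- function() {
  c(Glc = glucose_g_l_to_mm(6), Lac = 0.1, NH4 = 0.4,
    Ala = 1.0, Arg = 3.0, Asn = 4.5, Asp = 2.0, Cys = 1.0, Gln = 6.0,
    Glu = 4.0, Gly = 2.0, His = 1.5, Ile = 3.0, Leu = 4.5, Lys = 3.5,
    Met = 1.5, Phe = 2.5, Pro = 3.0, Ser = 4.0, Thr = 3.0, Trp = 1.0,
    Tyr = 2.0, Val = 3.5, GY = 0.5)
}

#' Dose-modulated specific rates
#'
#' Scales the byproduct-formation rates (lactate, ammonia, glutamate) down
#' and the amino-acid consumption rates up as the dose factor approaches
#' the optimum, leaving glucose uptake dose-independent (the study design
#' holds glucose uptake comparable across conditions).
#'
#' @param rates named base rates (pmol/cell/day).
#' @param gy_dose GY dose multiplier.
#' @return scaled rate vector.
#' @export
dose_scaled_rates <- function(rates, gy_dose) {
  f <- gy_dose_factor(gy_dose)
  prod <- intersect(c("Lac", "NH4", "Glu"), names(rates))
  cons <- setdiff(names(rates), c(prod, "Glc"))
  rates[prod] <- rates[prod] * (1.40 - 0.55 * f)
  rates[cons] <- rates[cons] * (0.80 + 0.25 * f)
  rates
}

#' Default graded-GY study design
#'
#' Five GY dose conditions in triplicate, matching the graded-dose
#' fed-batch design the downstream analysis expects; per-condition rates
#' come from [dose_scaled_rates()] and the GY dipeptide itself is simulated
#' as a residual species.
#'
#' @param doses GY dose multipliers.
#' @param noise_cv measurement noise CV.
#' @param n_replicates replicates per condition.
#' @return list of [condition_spec()].
#' @export
gy_conditions <- function(doses = c(0.125, 0.25, 0.5, 1, 2),
                          noise_cv = 0.05, n_replicates = 3) {
  lapply(doses, function(d)
    condition_spec(sprintf("GY_%gx", d), gy_dose = d,
                   base_rates = dose_scaled_rates(
                     c(default_base_rates(), GY = -0.03), d),
                   noise_cv = noise_cv, n_replicates = n_replicates))
}

## condition-level effective parameters from the dose-response
condition_effects <- function(cond) {
  f <- gy_dose_factor(cond$gy_dose)
  list(f = f,
       mu = cond$mu_max * (0.70 + 0.30 * f),
       x_max = cond$x_max * (0.45 + 0.55 * f),
       qp = cond$qp_max * (0.35 + 0.65 * f),
       decline = cond$decline_rate * (1.5 - 0.8 * f))
}

#' Simulate one fed-batch condition
#'
#' Cell density evolves on a 0.1-day grid (logistic growth to a peak near
#' day 8, then first-order decline; bolus events dilute cells by
#' `1/(1+f)`), while measured metabolite and titer trajectories advance
#' between consecutive sampling days through the trapezoidal IVCD of the
#' effective cell densities, so constant planted rates are exactly
#' recoverable from the emitted profiles at zero noise. Replicates differ
#' only by multiplicative lognormal measurement noise. Negative
#' concentrations are clipped to zero with a message.
#'
#' @param condition a [condition_spec()].
#' @param schedule a [feed_schedule()].
#' @param seed optional RNG seed (set it here or via [simulate_study()]).
#' @return a `culture_set`: list with `measurements` (batch_id,
#'   condition_id, day, variable, value) and `feed_events` (batch_id, day,
#'   bolus_fraction, metabolite, added_conc).
#' @export
simulate_fedbatch <- function(condition, schedule, seed = NULL) {
  if (!inherits(schedule, "feed_schedule")) stop("invalid feed schedule")
  if (!is.null(seed)) set.seed(seed)
  eff <- condition_effects(condition)
  ## planted nutrient-titer correlations act in rate space: extra formation
  ## (sign = -1) or consumption (sign = +1) of the metabolite in conditions
  ## away from the dose optimum, so its residual level tracks final titer
  ## with the requested sign through the culture's own mass balance
  for (p in condition$planted) {
    if (!p$metabolite %in% names(condition$base_rates)) next
    condition$base_rates[[p$metabolite]] <-
      condition$base_rates[[p$metabolite]] - p$sign * p$strength * (1 - eff$f)
  }
  dt <- 0.1
  days <- 0:14
  sdays <- SAMPLING_DAYS

  ## --- deterministic single trajectory -----------------------------------
  ## VCD on a fine grid; samples are drawn before the same-day bolus, the
  ## dilution applies immediately after. Piecewise-planted growth uses exact
  ## exponential steps so planted rates are recoverable to round-off.
  ph <- cbind(sdays[-length(sdays)], sdays[-1])
  phase_mu <- function(t) {
    k <- max(1, min(findInterval(t, ph[, 1]), nrow(ph)))
    condition$planted_mu[[paste0(ph[k, 1], "-", ph[k, 2])]]
  }
  Xc <- condition$inoculation_density
  vcd_meas <- stats::setNames(numeric(length(days)), days)
  for (d in days[-length(days)]) {
    vcd_meas[[as.character(d)]] <- Xc          # pre-feed sample
    if (d %in% schedule$bolus_days) Xc <- Xc / (1 + schedule$bolus_fraction)
    for (t in seq(d, d + 1 - dt, by = dt)) {
      if (!is.null(condition$planted_mu)) {
        Xc <- Xc * exp(phase_mu(t) * dt)
      } else {
        grow <- eff$mu * Xc * max(0, 1 - Xc / eff$x_max)
        die <- if (t >= condition$peak_day) eff$decline * Xc else 0
        Xc <- Xc + dt * (grow - die)
      }
    }
  }
  vcd_meas[[as.character(max(days))]] <- Xc
  vcd_at <- function(t) vcd_meas[[as.character(t)]]

  ## viability: high plateau, then decline after the peak (slower at the
  ## optimal dose)
  viability <- pmin(100, pmax(
    40, 98 - 0.35 * days - pmax(0, days - condition$peak_day) *
          (5.5 - 3.5 * eff$f)))

  ## sampling-day concentration/titer bookkeeping
  mets <- names(condition$base_rates)
  conc <- default_initial_conc()[mets]
  conc[is.na(conc)] <- 2
  names(conc) <- mets
  titer <- 0
  volume <- condition$volume_ml
  conc_tab <- matrix(NA_real_, length(sdays), length(mets),
                     dimnames = list(sdays, mets))
  titer_vec <- numeric(length(sdays))
  events <- list()
  clipped <- character()

  record <- function(k) { conc_tab[k, ] <<- conc; titer_vec[k] <<- titer }
  record(1)
  for (k in seq_len(length(sdays) - 1)) {
    t1 <- sdays[k]; t2 <- sdays[k + 1]
    v1 <- vcd_at(t1); v2 <- vcd_at(t2)
    ## feed-then-sample: the recorded day-t1 sample is pre-feed, so events
    ## at t1 are applied now, after record(k)
    if (t1 %in% schedule$bolus_days) {
      f <- schedule$bolus_fraction
      conc <- conc / (1 + f)
      titer <- titer / (1 + f)
      added <- schedule$feed_composition * f / (1 + f)
      if ("GY" %in% names(added)) added[["GY"]] <- added[["GY"]] * condition$gy_dose
      added <- added[names(added) %in% c(mets, "GY")]
      for (mname in intersect(names(added), mets))
        conc[[mname]] <- conc[[mname]] + added[[mname]]
      ## glucose setpoint top-up (concentrated stock, negligible volume)
      gs <- schedule$glucose_setpoints
      row <- which(t1 >= gs$from & t1 <= gs$to)
      if (length(row) && "Glc" %in% mets) {
        target <- glucose_g_l_to_mm(gs$target_g_l[row[1]])
        top <- max(0, target - conc[["Glc"]])
        added[["Glc"]] <- (if ("Glc" %in% names(added)) added[["Glc"]] else 0) + top
        conc[["Glc"]] <- conc[["Glc"]] + top
      }
      volume <- volume * (1 + f)
      events[[length(events) + 1]] <- data.frame(
        day = t1, bolus_fraction = f,
        metabolite = names(added), added_conc = unname(added))
    }
    ## advance by the trapezoidal IVCD of effective densities: the day-t1
    ## density entering the integral is the post-dilution one
    f1 <- if (t1 %in% schedule$bolus_days) schedule$bolus_fraction else 0
    ivcd <- (v1 / (1 + f1) + v2) / 2 * (t2 - t1)
    conc <- conc + condition$base_rates * ivcd
    neg <- conc < 0
    if (any(neg)) { clipped <- union(clipped, mets[neg]); conc[neg] <- 0 }
    titer <- titer + eff$qp * ivcd
    record(k + 1)
  }
  if (length(clipped))
    message(condition$condition_id, ": clipped negative concentrations for ",
            paste(clipped, collapse = ", "))


  ## --- replicate emission with measurement noise --------------------------
  meas <- list(); fe <- list()
  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(day = numeric(), bolus_fraction = numeric(),
               metabolite = character(), added_conc = numeric())
  for (r in seq_len(condition$n_replicates)) {
    bid <- paste0(condition$condition_id, "_b", r)
    noisy <- function(x) {
      if (condition$noise_cv == 0) return(x)
      sdl <- sqrt(log(1 + condition$noise_cv^2))
      x * exp(stats::rnorm(length(x), -sdl^2 / 2, sdl))
    }
    rows <- list(
      data.frame(day = days, variable = "VCD",
                 value = noisy(vapply(days, vcd_at, 0))),
      data.frame(day = days, variable = "viability",
                 value = pmin(100, noisy(viability))),
      data.frame(day = sdays, variable = "titer", value = noisy(titer_vec)))
    for (mname in mets)
      rows[[length(rows) + 1]] <- data.frame(
        day = sdays, variable = mname, value = noisy(conc_tab[, mname]))
    df <- do.call(rbind, rows)
    df <- data.frame(batch_id = bid, condition_id = condition$condition_id,
                     df, row.names = NULL)
    meas[[r]] <- df
    if (nrow(ev_df))
      fe[[r]] <- data.frame(batch_id = bid, ev_df, row.names = NULL)
  }
  structure(list(
    measurements = do.call(rbind, meas),
    feed_events = if (length(fe)) do.call(rbind, fe) else
      data.frame(batch_id = character(), day = numeric(),
                 bolus_fraction = numeric(), metabolite = character(),
                 added_conc = numeric()),
    conditions = stats::setNames(list(condition), condition$condition_id),
    schedule = schedule), class = "culture_set")
}

#' Simulate a multi-condition study
#'
#' @param conditions list of [condition_spec()] (default [gy_conditions()]).
#' @param schedule a [feed_schedule()].
#' @param seed RNG seed; the full dataset is deterministic given the seed.
#' @return a `culture_set` over all conditions.
#' @export
simulate_study <- function(conditions = gy_conditions(),
                           schedule = feed_schedule(), seed = 1) {
  set.seed(seed)
  sets <- lapply(conditions, simulate_fedbatch, schedule = schedule)
  structure(list(
    measurements = do.call(rbind, lapply(sets, `[[`, "measurements")),
    feed_events = do.call(rbind, lapply(sets, `[[`, "feed_events")),
    conditions = do.call(c, lapply(sets, `[[`, "conditions")),
    schedule = schedule), class = "culture_set")
}

#' @export
print.culture_set <- function(x, ...) {
  cat("culture_set: ", length(unique(x$measurements$batch_id)), " batches, ",
      length(x$conditions), " conditions, days ",
      min(x$measurements$day), "-", max(x$measurements$day), "\n", sep = "")
  invisible(x)
}

#' Plant a VCD outlier batch
#'
#' Multiplies one batch's entire VCD trajectory by `scale`, leaving all other
#' measurements untouched (test fixture for the outlier screen).
#'
#' @param set a `culture_set`.
#' @param target_batch_id batch to perturb.
#' @param scale positive multiplier (1 = no-op).
#' @return modified `culture_set`.
#' @export
plant_outlier <- function(set, target_batch_id, scale) {
  if (scale <= 0) stop("scale must be positive")
  m <- set$measurements
  idx <- m$batch_id == target_batch_id & m$variable == "VCD"
  if (!any(m$batch_id == target_batch_id))
    stop("unknown batch id: ", target_batch_id)
  m$value[idx] <- m$value[idx] * scale
  set$measurements <- m
  set
}

#' Plant a nutrient-titer correlation across conditions
#'
#' Shifts the metabolite's specific rate per condition by
#' `-sign * strength * (1 - dose_factor)` pmol/cell/day, i.e. extra
#' formation (for `sign = -1`) or extra consumption (for `sign = +1`) in
#' conditions away from the dose optimum. The residual concentration then
#' tracks final titer with the requested sign through the culture's own
#' mass balance, with batch-level magnitude set by each culture's IVCD.
#' Effect size: the rate shift is `strength * (1 - dose_factor)`
#' pmol/cell/day (zero at the optimal dose), accumulating to a terminal
#' concentration offset of roughly `strength x IVCD(0-14)` mM in the
#' extreme-dose conditions.
#'
#' @param conditions list of [condition_spec()].
#' @param metabolite simulated metabolite name (e.g. `"Glu"`).
#' @param sign `+1` or `-1`: requested sign of the correlation with titer.
#' @param strength rate-shift scale (pmol/cell/day at dose factor 0).
#' @return modified condition list.
#' @export
plant_titer_correlation <- function(conditions, metabolite, sign, strength) {
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  lapply(conditions, function(cond) {
    cond$planted[[length(cond$planted) + 1]] <-
      list(metabolite = metabolite, sign = sign, strength = strength)
    cond
  })
}

#' Write a culture set to CSV files
#'
#' @param set a `culture_set`.
#' @param dir output directory (created if needed); writes
#'   `measurements.csv` and `feed_events.csv` (UTF-8, dot decimal).
#' @return the directory, invisibly.
#' @export
write_culture_csv <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(set$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(set$feed_events, file.path(dir, "feed_events.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' Read a culture set from CSV files
#'
#' @param dir directory holding `measurements.csv` and `feed_events.csv`.
#' @return a `culture_set` (without condition specs).
#' @export
read_culture_csv <- function(dir) {
  structure(list(
    measurements = utils::read.csv(file.path(dir, "measurements.csv")),
    feed_events = utils::read.csv(file.path(dir, "feed_events.csv")),
    conditions = NULL, schedule = NULL), class = "culture_set")
}
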