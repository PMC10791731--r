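## Enzyme-capacity-constrained FBA -------------------------------------------

#' Convert a per-cell rate to a biomass-specific flux
#'
#' Bridges culture-derived specific rates (pmol/cell/day) to the flux unit of
#' genome-scale models (mmol/gDCW/h) via the cell dry weight.
#'
#' @param rate specific rate, pmol/cell/day (negative = consumption).
#' @param dcw_per_cell cell dry weight, pg/cell (default 250).
#' @return rate in mmol/gDCW/h, sign preserved.
#' @export
per_cell_to_specific <- function(rate, dcw_per_cell = 250) {
  if (any(dcw_per_cell <= 0)) stop("dcw_per_cell must be positive")
  rate * 1e-9 / (dcw_per_cell * 1e-12) / 24
}

#' Derive relaxed exchange bounds from measured rates
#'
#' Measured uptake/secretion rates are relaxed by a +/- fraction of their
#' magnitude (default 20%) and become the exchange-reaction bounds. A zero
#' measured rate yields a degenerate `[0, 0]` band, which is widened by an
#' absolute floor `epsilon` to avoid artificial infeasibility.
#'
#' @param rates named numeric vector, mmol/gDCW/h, names are exchange
#'   reaction ids; uptake negative.
#' @param relaxation relative relaxation fraction (default 0.2).
#' @param epsilon absolute widening applied to zero rates (mmol/gDCW/h).
#' @return data.frame reaction/rate/lb/ub.
#' @export
rate_constraints <- function(rates, relaxation = 0.2, epsilon = 1e-6) {
  lb <- rates - relaxation * abs(rates)
  ub <- rates + relaxation * abs(rates)
  zero <- rates == 0
  lb[zero] <- -epsilon
  ub[zero] <- epsilon
  data.frame(reaction = names(rates), rate = unname(rates),
             lb = unname(lb), ub = unname(ub))
}

#' Apply measured-rate bounds to a model
#'
#' Intersects the relaxed measured bands with the model's physical bounds.
#'
#' @param model a [metabolic_model()] (unsplit, signed bounds).
#' @param constraints data.frame from [rate_constraints()], or a named rate
#'   vector (then `...` is passed on to [rate_constraints()]).
#' @param ... passed to [rate_constraints()] when `constraints` is a vector.
#' @return model with updated exchange bounds.
#' @export
apply_rate_bounds <- function(model, constraints, ...) {
  if (is.numeric(constraints)) constraints <- rate_constraints(constraints, ...)
  unknown <- setdiff(constraints$reaction, names(model$reactions))
  if (length(unknown))
    stop("no such exchange reaction(s): ", paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(constraints))) {
    id <- constraints$reaction[i]
    r <- model$reactions[[id]]
    ## widen physical bounds that would make the measured band empty, then
    ## intersect: the measurement wins over default open bounds
    lb <- max(r$lb, constraints$lb[i])
    ub <- min(r$ub, constraints$ub[i])
    if (lb > ub) stop("measured band for '", id,
                      "' incompatible with physical bounds [", r$lb, ", ",
                      r$ub, "]")
    model$reactions[[id]]$lb <- lb
    model$reactions[[id]]$ub <- ub
  }
  model
}

#' Set the pooled enzyme-capacity budget
#'
#' Stores the total enzyme mass budget; at solve time a single pooled
#' constraint `sum_i (MW_i / kcat_i) v_i <= P_total` is added over all
#' kcat/MW-annotated reactions (GECKO-style protein pool). Reactions without
#' annotation are unconstrained by capacity.
#'
#' @param model a [metabolic_model()].
#' @param p_total enzyme budget, g/gDCW; `Inf` disables the constraint.
#' @return model with `p_total` set.
#' @export
apply_enzyme_capacity <- function(model, p_total) {
  annotated <- !is.na(reaction_field(model, "kcat")) &
               !is.na(reaction_field(model, "mw"))
  if (!any(annotated)) {
    warning("no kcat/MW annotations; enzyme-capacity constraint skipped")
    model$p_total <- NA_real_
    return(model)
  }
  model$p_total <- p_total
  model
}

capacity_row <- function(model_split) {
  kcat <- reaction_field(model_split, "kcat")
  mw <- reaction_field(model_split, "mw")
  w <- ifelse(!is.na(kcat) & !is.na(mw), mw / kcat, 0)
  w
}

#' Solve (ec)FBA with a parsimonious second stage
#'
#' Splits the model into irreversible reactions, maximizes the objective
#' reaction subject to steady state, bounds and (if `p_total` is set and
#' finite) the pooled enzyme-capacity constraint, then minimizes total
#' absolute flux at the fixed optimum so the returned flux vector is a
#' unique, reproducible representative (pFBA-style).
#'
#' @param model a [metabolic_model()] (signed bounds; split internally).
#' @param objective objective reaction id (default `model$objective`).
#' @param pfba run the parsimonious second stage (default TRUE).
#' @return `flux_solution`: list with `fluxes` (split, non-negative), `net`
#'   (per original reaction), `objective_value`, `status`, `total_flux`, and
#'   the split `model`.
#' @export
solve_fba <- function(model, objective = model$objective, pfba = TRUE) {
  if (is.null(objective)) stop("no objective reaction")
  ms <- if (is.null(model$split_map)) split_reversible(model) else model
  S <- stoich_matrix(ms)
  lb <- reaction_field(ms, "lb")
  ub <- reaction_field(ms, "ub")
  n <- length(lb)
  obj <- as.numeric(names(ms$reactions) == objective)
  if (!any(obj > 0)) stop("objective reaction '", objective, "' not in model")

  A_le <- NULL; b_le <- NULL
  if (!is.na(ms$p_total) && is.finite(ms$p_total)) {
    w <- capacity_row(ms)
    if (any(w > 0)) { A_le <- matrix(w, 1); b_le <- ms$p_total }
  }
  s1 <- solve_lp(obj, A_eq = S, b_eq = rep(0, nrow(S)), lb = lb, ub = ub,
                 A_le = A_le, b_le = b_le, maximize = TRUE)
  if (s1$status != "optimal") {
    bound_ids <- names(ms$reactions)[lb > 0 | ub < 1000]
    stop("FBA ", s1$status, "; constrained reactions: ",
         paste(utils::head(bound_ids, 20), collapse = ", "))
  }
  v <- s1$x
  opt <- s1$objective_value
  if (pfba) {
    ## fix the objective (within solver tolerance) and minimize total flux
    A2 <- matrix(obj, 1)
    s2 <- solve_lp(rep(1, n), A_eq = S, b_eq = rep(0, nrow(S)),
                   lb = pmax(lb, obj * opt * (1 - 1e-9)), ub = ub,
                   A_le = A_le, b_le = b_le, maximize = FALSE)
    if (s2$status == "optimal") v <- s2$x
  }
  names(v) <- names(ms$reactions)
  check_solution(ms, v)
  structure(list(fluxes = v, net = net_fluxes(v, ms),
                 objective_value = opt, status = "optimal",
                 total_flux = sum(v), model = ms),
            class = "flux_solution")
}

check_solution <- function(model_split, v, tol_ss = 1e-6, tol_b = 1e-8) {
  S <- stoich_matrix(model_split)
  resid <- max(abs(S %*% v))
  if (resid > tol_ss) stop("steady-state violation: max |S v| = ", resid)
  lb <- reaction_field(model_split, "lb"); ub <- reaction_field(model_split, "ub")
  if (any(v < lb - tol_b) || any(v > ub + tol_b))
    stop("bound violation in flux solution")
  invisible(TRUE)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution: objective ", format(x$objective_value, digits = 6),
      ", total |flux| ", format(x$total_flux, digits = 6),
      ", ", length(x$fluxes), " irreversible reactions\n", sep = "")
  invisible(x)
}

#' Solve ecFBA with a fixed antibody flux
#'
#' Fixes the IgG synthesis flux to its measured value (lb = ub), optionally
#' caps growth, and maximizes biomass.
#'
#' @param model a [metabolic_model()] with measured-rate bounds applied.
#' @param igg_flux measured antibody synthesis flux, mmol residues/gDCW/h.
#' @param growth_cap optional upper bound on the biomass reaction (1/h).
#' @param igg_reaction id of the antibody synthesis reaction.
#' @param ... passed to [solve_fba()].
#' @return a `flux_solution`.
#' @export
solve_ecfba <- function(model, igg_flux, growth_cap = NULL,
                        igg_reaction = "IGGSYN", ...) {
  if (!igg_reaction %in% names(model$reactions))
    stop("no antibody reaction '", igg_reaction, "' in model")
  if (igg_flux < 0) stop("igg_flux must be non-negative")
  model$reactions[[igg_reaction]]$lb <- igg_flux
  model$reactions[[igg_reaction]]$ub <- igg_flux
  if (!is.null(growth_cap))
    model$reactions[[model$objective]]$ub <-
      min(model$reactions[[model$objective]]$ub, growth_cap)
  solve_fba(model, ...)
}

#' Condition-level flux state from replicate rates
#'
#' Solves ecFBA once per replicate and averages fluxes reaction-wise, giving
#' the condition-representative flux state. Infeasible replicates are skipped
#' with a warning; if all replicates are infeasible an error is raised.
#'
#' @param model base model (bounds not yet applied).
#' @param replicate_rates list, one named rate vector (mmol/gDCW/h, exchange
#'   ids) per replicate.
#' @param igg_fluxes numeric, one measured antibody flux per replicate.
#' @param relaxation,epsilon passed to [rate_constraints()].
#' @param ... passed to [solve_ecfba()].
#' @return a `flux_solution` with averaged `fluxes` and `net`.
#' @export
condition_flux <- function(model, replicate_rates, igg_fluxes,
                           relaxation = 0.2, epsilon = 1e-6, ...) {
  stopifnot(length(replicate_rates) == length(igg_fluxes))
  sols <- list()
  for (i in seq_along(replicate_rates)) {
    s <- tryCatch({
      m <- apply_rate_bounds(model, replicate_rates[[i]],
                             relaxation = relaxation, epsilon = epsilon)
      solve_ecfba(m, igg_fluxes[[i]], ...)
    }, error = function(e) {
      warning("replicate ", i, " infeasible: ", conditionMessage(e))
      NULL
    })
    if (!is.null(s)) sols[[length(sols) + 1L]] <- s
  }
  if (!length(sols)) stop("all replicates infeasible")
  avg <- Reduce(`+`, lapply(sols, `[[`, "fluxes")) / length(sols)
  out <- sols[[1]]
  out$fluxes <- avg
  out$net <- net_fluxes(avg, out$model)
  out$objective_value <- mean(vapply(sols, `[[`, 0, "objective_value"))
  out$total_flux <- sum(avg)
  out$n_replicates <- length(sols)
  out
}
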