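# Boltzmann-weighted multi-simulation LIE prediction.
#
# The binding free energy is a linear response expression in the ensemble-
# averaged bound-minus-unbound ligand-surrounding interaction energies,
#   dG_pred = alpha * sum_i W_i dV_i^vdw + beta * sum_i W_i dV_i^ele + gamma,
# where i runs over independent simulations (replicate MD runs started from
# different docking poses) and W_i is the Boltzmann weight of simulation i
# computed from its own single-simulation prediction dG_pred,i.

#' Bound-minus-unbound interaction-energy differences
#'
#' One (dV_vdw, dV_ele) pair per bound simulation: the bound ensemble average
#' minus the unbound solvated-ligand reference, in input order.
#'
#' @param energetics a [compound_energetics()].
#' @return data.frame with columns `pose`, `replicate`, `dv_vdw`, `dv_ele`.
#' @export
delta_interactions <- function(energetics) {
  stopifnot(inherits(energetics, "compound_energetics"))
  b <- energetics$bound
  data.frame(pose = b$pose, replicate = b$replicate,
             dv_vdw = b$mean_vdw - energetics$unbound[["mean_vdw"]],
             dv_ele = b$mean_ele - energetics$unbound[["mean_ele"]],
             stringsAsFactors = FALSE)
}

#' Single-simulation LIE prediction
#'
#' `alpha * dv_vdw + beta * dv_ele + gamma`, vectorised over simulations.
#'
#' @param params [lie_parameters()].
#' @param dv_vdw,dv_ele interaction-energy differences (kJ/mol).
#' @return Predicted binding free energies (kJ/mol).
#' @export
per_simulation_dg <- function(params, dv_vdw, dv_ele) {
  stopifnot(inherits(params, "lie_parameters"))
  params$alpha * dv_vdw + params$beta * dv_ele + params$gamma
}

#' Boltzmann weights over simulations
#'
#' `W_i = exp(-dG_i / RT) / sum_j exp(-dG_j / RT)`. Computed with a max-shift
#' so arbitrarily negative free energies cannot overflow; invariant under
#' adding a constant to all dG values. Lower predicted free energy (stronger
#' predicted binding) receives higher weight.
#'
#' @param dg numeric vector of per-simulation predicted free energies
#'   (kJ/mol); must be non-empty.
#' @param temperature temperature in K.
#' @return Weights summing to 1.
#' @export
boltzmann_weights <- function(dg, temperature = 300) {
  if (length(dg) == 0L) stop("boltzmann_weights: empty free-energy list")
  if (!all(is.finite(dg))) stop("boltzmann_weights: non-finite free energy")
  if (temperature <= 0) stop("temperature must be positive")
  x <- -dg / (GAS_CONSTANT_KJ * temperature)
  e <- exp(x - max(x))
  e / sum(e)
}

#' Boltzmann-weighted LIE prediction for one compound
#'
#' Evaluates the single-simulation prediction for every bound run, converts
#' them to Boltzmann weights, and returns the weighted free energy together
#' with the per-simulation breakdown. The result is a convex combination of
#' the per-simulation predictions and is invariant under permutation of the
#' simulations.
#'
#' @param params [lie_parameters()].
#' @param energetics a [compound_energetics()].
#' @return An object of class `lie_prediction`: list with `compound_id`,
#'   `dg_pred` (kJ/mol), and `per_simulation` (data.frame with `dv_vdw`,
#'   `dv_ele`, `dg_i`, `weight`).
#' @export
lie_predict <- function(params, energetics) {
  stopifnot(inherits(params, "lie_parameters"),
            inherits(energetics, "compound_energetics"))
  dv <- delta_interactions(energetics)
  dg_i <- per_simulation_dg(params, dv$dv_vdw, dv$dv_ele)
  w <- boltzmann_weights(dg_i, params$temperature)
  per <- cbind(dv, dg_i = dg_i, weight = w)
  structure(list(compound_id = energetics$compound_id,
                 dg_pred = sum(w * dg_i),
                 per_simulation = per),
            class = "lie_prediction")
}

#' @export
print.lie_prediction <- function(x, ...) {
  cat(sprintf("<lie_prediction> %s: dG_pred = %.3f kJ/mol over %d simulation(s)\n",
              x$compound_id, x$dg_pred, nrow(x$per_simulation)))
  invisible(x)
}

#' Boltzmann-weighted interaction-energy pair
#'
#' The weighted sums `(sum_i W_i dV_i^vdw, sum_i W_i dV_i^ele)` under the
#' supplied parameters. These are the regressors of the LIE model at the
#' current weights and the energy descriptor used by the applicability-domain
#' assessment.
#'
#' @inheritParams lie_predict
#' @return Named numeric vector `c(dv_vdw =, dv_ele =)` (kJ/mol).
#' @export
weighted_interactions <- function(params, energetics) {
  pred <- lie_predict(params, energetics)
  per <- pred$per_simulation
  c(dv_vdw = sum(per$weight * per$dv_vdw),
    dv_ele = sum(per$weight * per$dv_ele))
}
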