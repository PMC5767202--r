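# Iterative weighted-OLS calibration of the LIE parameters, cross-validation
# and quality metrics.
#
# The weights of the multi-simulation prediction depend on the parameters
# being fitted, so calibration alternates between (a) computing Boltzmann
# weights and weighted design rows under the current parameters and (b) an
# ordinary least-squares fit of alpha, beta (and optionally gamma) to the
# observed free energies, starting from uniform weights. Step-halving towards
# the previous accepted parameters is applied if a full update increases the
# sum of squared residuals.

#' Cheng-Prusoff estimate of the observed binding free energy
#'
#' Converts an IC50 (molar) to an approximate binding free energy,
#' `dG_obs = RT ln(IC50)`. The substrate-concentration correction term is not
#' applied (assay conditions are typically unavailable), so the estimate is
#' the IC50 treated as an effective dissociation constant.
#'
#' @param ic50 IC50 in molar units; must be positive. Vectorised.
#' @param temperature temperature in K.
#' @return Binding free energy estimate(s) in kJ/mol.
#' @examples
#' cheng_prusoff_dg(1e-9)  # a 1 nM inhibitor, about -51.7 kJ/mol at 300 K
#' @export
cheng_prusoff_dg <- function(ic50, temperature = 300) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 values must be positive and finite (molar units)")
  if (temperature <= 0) stop("temperature must be positive")
  GAS_CONSTANT_KJ * temperature * log(ic50)
}

#' LIE design row at given parameters
#'
#' The regressor pair `(sum_i W_i dV_i^vdw, sum_i W_i dV_i^ele)` with weights
#' computed under `params`. For a single-simulation compound this is the raw
#' Delta-V pair; for equal per-simulation predictions it is the unweighted
#' mean.
#'
#' @inheritParams lie_predict
#' @return Named numeric vector `c(x_vdw =, x_ele =)`.
#' @export
design_row <- function(params, energetics) {
  w <- weighted_interactions(params, energetics)
  c(x_vdw = unname(w[["dv_vdw"]]), x_ele = unname(w[["dv_ele"]]))
}

#' Ordinary least-squares fit of the LIE parameters
#'
#' Minimises `sum (dg_obs - alpha x_vdw - beta x_ele - gamma)^2`. With
#' `include_offset = FALSE` gamma is fixed to 0.
#'
#' @param x_vdw,x_ele regressor vectors (weighted interaction-energy sums).
#' @param dg_obs observed binding free energies (kJ/mol).
#' @param include_offset fit the constant offset gamma?
#' @param temperature stored in the returned parameters.
#' @return [lie_parameters()] with attribute `se` (standard errors, named
#'   alpha/beta/gamma) and attribute `fit` (the `lm` object).
#' @export
fit_ols <- function(x_vdw, x_ele, dg_obs, include_offset = TRUE,
                    temperature = 300) {
  n <- length(dg_obs)
  stopifnot(length(x_vdw) == n, length(x_ele) == n)
  p <- if (include_offset) 3L else 2L
  if (n < p)
    stop(sprintf("need at least %d compounds to fit %d parameters", p, p))
  dat <- data.frame(dg_obs = dg_obs, x_vdw = x_vdw, x_ele = x_ele)
  fml <- if (include_offset) dg_obs ~ x_vdw + x_ele
         else dg_obs ~ x_vdw + x_ele - 1
  X <- stats::model.matrix(fml, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  # vcov warns on interpolating (zero-residual) fits; the ~0 errors are valid
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  params <- lie_parameters(
    alpha = cf[["x_vdw"]], beta = cf[["x_ele"]],
    gamma = if (include_offset) cf[["(Intercept)"]] else 0,
    temperature = temperature)
  se_out <- c(alpha = unname(se[["x_vdw"]]), beta = unname(se[["x_ele"]]),
              gamma = if (include_offset) unname(se[["(Intercept)"]]) else 0)
  attr(params, "se") <- se_out
  attr(params, "fit") <- fit
  params
}

params_vec <- function(p) c(alpha = p$alpha, beta = p$beta, gamma = p$gamma)

sse_at <- function(params, energetics_list, dg_obs) {
  pred <- vapply(energetics_list,
                 function(e) lie_predict(params, e)$dg_pred, numeric(1))
  sum((dg_obs - pred)^2)
}

#' Iterative calibration of a multi-pose LIE model
#'
#' Alternates Boltzmann-weight computation and OLS fitting until the maximum
#' absolute parameter change falls below `tol` or `max_iter` is reached.
#' Starts from uniform weights, so a training set of single-simulation
#' compounds reduces to one plain OLS fit. If a full parameter update would
#' increase the self-consistent sum of squared residuals, the step is halved
#' towards the previous accepted parameters (recorded in the result as
#' `damped`). Non-convergence is reported via `converged = FALSE`, not as an
#' error.
#'
#' @param training list of [training_compound()] objects (or of
#'   `compound_energetics` paired with `dg_obs` via the `dg_obs` argument).
#' @param temperature temperature in K for the Boltzmann weights.
#' @param include_offset fit gamma? Requires >= 3 compounds (>= 2 otherwise).
#' @param tol convergence tolerance on the maximum parameter change.
#' @param max_iter iteration cap.
#' @return An object of class `lie_model`: parameters, per-compound training
#'   summary (`compound_id`, `dg_obs`, `dg_pred`), quality `metrics` (RMSE,
#'   Pearson r, Spearman rho), `n_iterations`, `converged`, `damped`,
#'   parameter standard errors `se`, and provenance.
#' @export
calibrate_lie <- function(training, temperature = 300, include_offset = TRUE,
                          tol = 1e-6, max_iter = 100) {
  stopifnot(is.list(training), length(training) >= 1L)
  if (!all(vapply(training, inherits, logical(1), "training_compound")))
    stop("training must be a list of training_compound objects")
  n <- length(training)
  p <- if (include_offset) 3L else 2L
  if (n < p)
    stop(sprintf("iterative calibration needs at least %d compounds", p))
  dg_obs <- vapply(training, function(tc) tc$dg_obs, numeric(1))
  energetics <- lapply(training, function(tc) tc$energetics)
  ids <- vapply(training, function(tc) tc$compound_id, character(1))

  # uniform-weight design rows to seed the loop
  dv <- lapply(energetics, delta_interactions)
  rows <- t(vapply(dv, function(d) c(mean(d$dv_vdw), mean(d$dv_ele)),
                   numeric(2)))
  params <- fit_ols(rows[, 1], rows[, 2], dg_obs, include_offset, temperature)
  obj <- sse_at(params, energetics, dg_obs)

  converged <- FALSE
  damped <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    rows <- t(vapply(energetics, function(e) design_row(params, e), numeric(2)))
    cand <- fit_ols(rows[, 1], rows[, 2], dg_obs, include_offset, temperature)
    cand_obj <- sse_at(cand, energetics, dg_obs)
    if (cand_obj > obj + 1e-12) {
      # damp: halve the step towards the previous accepted parameters
      damped <- TRUE
      prev <- params_vec(params)
      step <- params_vec(cand) - prev
      for (h in 1:25) {
        step <- step / 2
        trial_vec <- prev + step
        trial <- lie_parameters(trial_vec[["alpha"]], trial_vec[["beta"]],
                                trial_vec[["gamma"]], temperature)
        trial_obj <- sse_at(trial, energetics, dg_obs)
        if (trial_obj <= obj + 1e-12) break
      }
      attr(trial, "se") <- attr(cand, "se")
      cand <- trial
      cand_obj <- trial_obj
    }
    delta <- max(abs(params_vec(cand) - params_vec(params)))
    params <- cand
    obj <- cand_obj
    if (delta < tol) { converged <- TRUE; break }
  }

  preds <- vapply(energetics, function(e) lie_predict(params, e)$dg_pred,
                  numeric(1))
  metrics <- quality_metrics(dg_obs, preds)
  structure(list(
    parameters = params,
    include_offset = include_offset,
    training = data.frame(compound_id = ids, dg_obs = dg_obs, dg_pred = preds,
                          stringsAsFactors = FALSE),
    metrics = metrics,
    se = attr(params, "se"),
    n_iterations = iter,
    converged = converged,
    damped = damped,
    ad_reference = NULL,
    provenance = list(package = "ilie",
                      version = as.character(utils::packageVersion("ilie")),
                      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), class = "lie_model")
}

#' @export
print.lie_model <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<lie_model> alpha = %.4g, beta = %.4g, gamma = %.4g kJ/mol (T = %g K)\n",
              p$alpha, p$beta, p$gamma, p$temperature))
  cat(sprintf("  n = %d compounds; RMSE = %.3f kJ/mol; r = %.3f; rho = %.3f\n",
              nrow(x$training), x$metrics$rmse, x$metrics$r_pearson,
              x$metrics$rho_spearman))
  cat(sprintf("  %d iteration(s); converged: %s%s; AD reference: %s\n",
              x$n_iterations, x$converged,
              if (isTRUE(x$damped)) " (damped)" else "",
              !is.null(x$ad_reference)))
  invisible(x)
}

#' Predict binding free energies with a fitted model
#'
#' @param object a `lie_model`.
#' @param newdata a [compound_energetics()] or a list of them.
#' @param ... unused.
#' @return A single `lie_prediction` or a list of them.
#' @export
predict.lie_model <- function(object, newdata, ...) {
  if (inherits(newdata, "compound_energetics"))
    return(lie_predict(object$parameters, newdata))
  lapply(newdata, function(e) lie_predict(object$parameters, e))
}

#' Leave-one-out standard error of prediction
#'
#' For each training compound, the full iterative calibration is refitted on
#' the remaining n-1 compounds and the held-out compound is predicted with
#' the refitted parameters; SDEP is the root mean squared held-out error. The
#' held-out compound never contributes to weight or parameter estimation.
#'
#' @inheritParams calibrate_lie
#' @return List with `sdep_loo` (kJ/mol) and per-compound `loo_predictions`.
#' @export
loo_sdep <- function(training, temperature = 300, include_offset = TRUE,
                     tol = 1e-6, max_iter = 100) {
  n <- length(training)
  if (n < 4L) stop("leave-one-out cross-validation needs at least 4 compounds")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- calibrate_lie(training[-i], temperature = temperature,
                         include_offset = include_offset, tol = tol,
                         max_iter = max_iter)
    preds[i] <- lie_predict(fit$parameters, training[[i]]$energetics)$dg_pred
  }
  dg_obs <- vapply(training, function(tc) tc$dg_obs, numeric(1))
  list(sdep_loo = sqrt(mean((dg_obs - preds)^2)),
       loo_predictions = data.frame(
         compound_id = vapply(training, function(tc) tc$compound_id,
                              character(1)),
         dg_obs = dg_obs, dg_pred_loo = preds, stringsAsFactors = FALSE))
}

#' Regression quality metrics
#'
#' Root-mean-square error, standard error of prediction (the same formula,
#' reported under the name used for held-out sets), Pearson r and Spearman
#' rho (average ranks for ties). Correlations are undefined (NA) when either
#' vector has zero variance.
#'
#' @param obs,pred equal-length numeric vectors, n >= 2.
#' @return List with `rmse`, `sdep`, `r_pearson`, `rho_spearman`.
#' @export
quality_metrics <- function(obs, pred) {
  n <- length(obs)
  stopifnot(length(pred) == n, n >= 2L)
  rmse <- sqrt(mean((obs - pred)^2))
  zero_var <- stats::sd(obs) == 0 || stats::sd(pred) == 0
  r <- if (zero_var) NA_real_ else stats::cor(obs, pred, method = "pearson")
  rho <- if (zero_var) NA_real_ else stats::cor(obs, pred, method = "spearman")
  list(rmse = rmse, sdep = rmse, r_pearson = r, rho_spearman = rho)
}
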