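# Shared domain types and I/O for the iterative LIE workflow.
# All energies are carried in kJ/mol; times in ps; no function converts units.

#' Molar gas constant in kJ mol^-1 K^-1
#'
#' Used wherever a thermal energy RT enters (Boltzmann weights, the
#' Cheng-Prusoff conversion).
#'
#' @export
GAS_CONSTANT_KJ <- 0.0083145

#' Interaction-energy time series for one simulation
#'
#' Holds the ligand-surrounding van der Waals and electrostatic interaction
#' energies written out along a molecular dynamics trajectory (typically every
#' 10 ps of a 1 ns production run).
#'
#' @param time_ps numeric vector of frame times in ps, strictly increasing.
#' @param v_vdw numeric vector of van der Waals interaction energies (kJ/mol).
#' @param v_ele numeric vector of electrostatic interaction energies (kJ/mol).
#' @return An object of class `energy_trace`.
#' @examples
#' tr <- energy_trace(c(10, 20, 30), c(-10, -20, -30), c(-5, -5, -5))
#' average_trace(tr, burn_in = 10)
#' @export
energy_trace <- function(time_ps, v_vdw, v_ele) {
  time_ps <- as.numeric(time_ps)
  v_vdw <- as.numeric(v_vdw)
  v_ele <- as.numeric(v_ele)
  n <- length(time_ps)
  if (n < 1L) stop("energy_trace needs at least one frame")
  if (length(v_vdw) != n || length(v_ele) != n)
    stop("time_ps, v_vdw and v_ele must have equal length")
  if (anyNA(time_ps) || any(!is.finite(c(v_vdw, v_ele))))
    stop("energy_trace values must be finite")
  if (n > 1L && any(diff(time_ps) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(time_ps = time_ps, v_vdw = v_vdw, v_ele = v_ele),
            class = "energy_trace")
}

#' Ensemble-average a trace
#'
#' Arithmetic mean of the van der Waals and electrostatic energies over all
#' frames with time strictly greater than `burn_in`. The mean is independent
#' of frame order and linear in the energies.
#'
#' @param trace an [energy_trace()].
#' @param burn_in equilibration time to discard, in ps (default 0: average the
#'   full production trajectory).
#' @return Named numeric vector `c(mean_vdw =, mean_ele =)` in kJ/mol.
#' @export
average_trace <- function(trace, burn_in = 0) {
  stopifnot(inherits(trace, "energy_trace"))
  if (!is.numeric(burn_in) || length(burn_in) != 1L || burn_in < 0)
    stop("burn_in must be a single non-negative time in ps")
  keep <- trace$time_ps > burn_in
  if (!any(keep))
    stop(sprintf("no frames left after burn_in = %g ps (trace ends at %g ps)",
                 burn_in, max(trace$time_ps)))
  c(mean_vdw = mean(trace$v_vdw[keep]), mean_ele = mean(trace$v_ele[keep]))
}

#' Bound and unbound interaction energetics of one compound
#'
#' Collects the ensemble-averaged bound-state energies of all independent
#' simulations of a compound (one or more replicate MD runs per docking pose)
#' together with the unbound solvated-ligand reference averages. The
#' bound-minus-unbound differences are the Delta-V inputs of the LIE model.
#'
#' @param compound_id identifier.
#' @param bound data.frame with columns `pose`, `replicate`, `mean_vdw`,
#'   `mean_ele` (kJ/mol), one row per independent bound-state simulation.
#' @param unbound_vdw,unbound_ele unbound reference averages (kJ/mol).
#' @return An object of class `compound_energetics`.
#' @export
compound_energetics <- function(compound_id, bound, unbound_vdw, unbound_ele) {
  stopifnot(is.data.frame(bound))
  req <- c("pose", "replicate", "mean_vdw", "mean_ele")
  miss <- setdiff(req, names(bound))
  if (length(miss))
    stop("bound table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(bound) < 1L) stop("at least one bound simulation is required")
  if (any(!is.finite(bound$mean_vdw)) || any(!is.finite(bound$mean_ele)))
    stop("bound means must be finite")
  if (!is.finite(unbound_vdw) || !is.finite(unbound_ele))
    stop("unbound means must be finite")
  key <- paste(bound$pose, bound$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (pose, replicate) bound records for compound ", compound_id)
  structure(list(compound_id = as.character(compound_id),
                 bound = bound[req],
                 unbound = c(mean_vdw = as.numeric(unbound_vdw),
                             mean_ele = as.numeric(unbound_ele))),
            class = "compound_energetics")
}

#' @export
print.compound_energetics <- function(x, ...) {
  cat(sprintf("<compound_energetics> %s: %d bound simulation(s), unbound (%.2f, %.2f) kJ/mol\n",
              x$compound_id, nrow(x$bound), x$unbound[["mean_vdw"]],
              x$unbound[["mean_ele"]]))
  invisible(x)
}

#' LIE model parameters
#'
#' The empirical scaling parameters of the linear interaction energy model:
#' `alpha` scales the van der Waals difference, `beta` the electrostatic
#' difference, and `gamma` is an optional constant offset (kJ/mol). The
#' temperature defines the thermal energy RT used in Boltzmann weighting.
#'
#' @param alpha,beta dimensionless scaling parameters.
#' @param gamma offset in kJ/mol.
#' @param temperature simulation temperature in K (default 300).
#' @return An object of class `lie_parameters`.
#' @export
lie_parameters <- function(alpha, beta, gamma = 0, temperature = 300) {
  vals <- c(alpha, beta, gamma, temperature)
  if (length(vals) != 4L || any(!is.finite(vals)))
    stop("alpha, beta, gamma and temperature must be single finite numbers")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma),
                 temperature = as.numeric(temperature)),
            class = "lie_parameters")
}

#' @export
print.lie_parameters <- function(x, ...) {
  cat(sprintf("<lie_parameters> alpha = %.4g, beta = %.4g, gamma = %.4g kJ/mol, T = %g K\n",
              x$alpha, x$beta, x$gamma, x$temperature))
  invisible(x)
}

#' Training compound: observed affinity plus simulation data
#'
#' @param compound_id identifier.
#' @param dg_obs observed binding free energy (kJ/mol).
#' @param energetics a [compound_energetics()].
#' @param fingerprint optional 0/1 (or logical) bit vector for similarity
#'   assessment.
#' @param decomposition_vdw,decomposition_ele optional per-residue
#'   decompositions of the van der Waals / electrostatic interaction energy
#'   (kJ/mol); all compounds of a set must share one residue ordering.
#' @return An object of class `training_compound`.
#' @export
training_compound <- function(compound_id, dg_obs, energetics,
                              fingerprint = NULL,
                              decomposition_vdw = NULL,
                              decomposition_ele = NULL) {
  stopifnot(inherits(energetics, "compound_energetics"))
  if (!is.finite(dg_obs)) stop("dg_obs must be finite")
  if (!is.null(fingerprint)) {
    fingerprint <- as.integer(fingerprint)
    if (any(is.na(fingerprint)) || any(!fingerprint %in% c(0L, 1L)))
      stop("fingerprint must be a 0/1 bit vector")
  }
  structure(list(compound_id = as.character(compound_id),
                 dg_obs = as.numeric(dg_obs),
                 energetics = energetics,
                 fingerprint = fingerprint,
                 decomposition_vdw = decomposition_vdw,
                 decomposition_ele = decomposition_ele),
            class = "training_compound")
}

# ---- energy table I/O -------------------------------------------------------

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a long-form interaction-energy table
#'
#' The canonical exchange format is delimited text (comma or tab,
#' autodetected) with header columns `compound, pose, replicate, state,
#' time_ps, v_vdw, v_ele`; `state` is `bound` or `unbound`, and each row is
#' one trajectory frame. Frames are averaged per simulation (after an
#' optional burn-in) and grouped into one [compound_energetics()] per
#' compound.
#'
#' @param path file path.
#' @param burn_in equilibration time (ps) discarded before averaging.
#' @return Named list of `compound_energetics`, one element per compound.
#' @export
read_energy_table <- function(path, burn_in = 0) {
  if (!file.exists(path)) stop("energy table not found: ", path)
  sep <- detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  req <- c("compound", "pose", "replicate", "state", "time_ps", "v_vdw", "v_ele")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("energy table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("time_ps", "v_vdw", "v_ele")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d", col, bad[1L]))
    raw[[col]] <- num
  }
  badstate <- which(!raw$state %in% c("bound", "unbound"))
  if (length(badstate))
    stop(sprintf("unknown state '%s' at data row %d (must be bound/unbound)",
                 raw$state[badstate[1L]], badstate[1L]))
  key <- paste(raw$compound, raw$pose, raw$replicate, raw$state, raw$time_ps,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (compound, pose, replicate, state, time) at data row %d",
                 dup[1L]))

  out <- list()
  for (cid in unique(raw$compound)) {
    sub <- raw[raw$compound == cid, , drop = FALSE]
    unb <- sub[sub$state == "unbound", , drop = FALSE]
    bnd <- sub[sub$state == "bound", , drop = FALSE]
    if (nrow(unb) == 0L)
      stop("no unbound reference for compound ", cid)
    if (nrow(bnd) == 0L)
      stop("no bound simulations for compound ", cid)
    mean_sim <- function(d) {
      tr <- d[order(d$time_ps), , drop = FALSE]
      m <- average_trace(energy_trace(tr$time_ps, tr$v_vdw, tr$v_ele), burn_in)
      data.frame(mean_vdw = m[["mean_vdw"]], mean_ele = m[["mean_ele"]])
    }
    # unbound: averaged over all unbound replicate runs
    unb_runs <- split(unb, paste(unb$pose, unb$replicate, sep = "\r"))
    unb_means <- do.call(rbind, lapply(unb_runs, mean_sim))
    runs <- split(bnd, paste(bnd$pose, bnd$replicate, sep = "\r"))
    bound <- do.call(rbind, lapply(runs, function(d) {
      cbind(data.frame(pose = d$pose[1L], replicate = d$replicate[1L],
                       stringsAsFactors = FALSE), mean_sim(d))
    }))
    rownames(bound) <- NULL
    out[[cid]] <- compound_energetics(cid, bound,
                                      mean(unb_means$mean_vdw),
                                      mean(unb_means$mean_ele))
  }
  out
}

#' Read a training table
#'
#' CSV with a `compound_id` column plus exactly one of `ic50_molar`
#' (converted to a binding free energy with [cheng_prusoff_dg()]) or
#' `dg_obs_kjmol`.
#'
#' @param path file path.
#' @param temperature temperature (K) for the IC50 conversion.
#' @return data.frame with columns `compound_id`, `dg_obs`.
#' @export
read_training_table <- function(path, temperature = 300) {
  if (!file.exists(path)) stop("training table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"compound_id" %in% names(tab))
    stop("training table missing column: compound_id")
  has_ic50 <- "ic50_molar" %in% names(tab)
  has_dg <- "dg_obs_kjmol" %in% names(tab)
  if (has_ic50 == has_dg)
    stop("training table must have exactly one of ic50_molar or dg_obs_kjmol")
  dg <- if (has_dg) as.numeric(tab$dg_obs_kjmol)
        else cheng_prusoff_dg(as.numeric(tab$ic50_molar), temperature)
  data.frame(compound_id = as.character(tab$compound_id), dg_obs = dg,
             stringsAsFactors = FALSE)
}

# ---- model file I/O ---------------------------------------------------------

MODEL_SCHEMA <- "ilie-model"
MODEL_SCHEMA_VERSION <- 1L

#' Write a fitted LIE model to a versioned JSON file
#'
#' Serialises parameters, the training summary, the optional
#' applicability-domain reference and provenance. [read_lie_model()] restores
#' the object; numeric fields round-trip to within 1e-12.
#'
#' @param model a `lie_model` (from [calibrate_lie()]), optionally carrying an
#'   `ad_reference`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lie_model <- function(model, path) {
  stopifnot(inherits(model, "lie_model"))
  payload <- list(
    schema = MODEL_SCHEMA,
    schema_version = MODEL_SCHEMA_VERSION,
    parameters = unclass(model$parameters),
    include_offset = model$include_offset,
    training = model$training,
    metrics = model$metrics,
    n_iterations = model$n_iterations,
    converged = model$converged,
    damped = model$damped,
    ad_reference = if (!is.null(model$ad_reference))
      ad_reference_to_list(model$ad_reference),
    provenance = model$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a LIE model written by [write_lie_model()]
#'
#' @param path JSON file path.
#' @return A `lie_model` object.
#' @export
read_lie_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema) || payload$schema != MODEL_SCHEMA)
    stop("not an ilie model file: ", path)
  if (is.null(payload$schema_version) ||
      payload$schema_version != MODEL_SCHEMA_VERSION)
    stop(sprintf("unsupported model schema version %s (expected %d)",
                 payload$schema_version, MODEL_SCHEMA_VERSION))
  p <- payload$parameters
  model <- structure(list(
    parameters = lie_parameters(p$alpha, p$beta, p$gamma, p$temperature),
    include_offset = isTRUE(payload$include_offset),
    training = as.data.frame(payload$training),
    metrics = payload$metrics,
    n_iterations = payload$n_iterations,
    converged = isTRUE(payload$converged),
    damped = isTRUE(payload$damped),
    ad_reference = if (!is.null(payload$ad_reference))
      ad_reference_from_list(payload$ad_reference),
    provenance = payload$provenance
  ), class = "lie_model")
  model
}
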