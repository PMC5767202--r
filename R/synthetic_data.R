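# Synthetic-data generator with known ground truth.
#
# Every stage of the workflow (prediction, calibration, AD assessment, pose
# clustering) can be exercised without docking or MD: compounds are drawn
# from the forward model itself, so the generating parameters are the known
# truth that calibration must recover. One global seed governs all draws;
# deterministic sub-seeds are derived per component so modules can be
# regenerated independently.

sub_seed <- function(seed, k) (abs(seed) + 1000003 * k) %% 2147483647

#' Specification of a synthetic LIE data set
#'
#' Defaults describe a realistic small-molecule training campaign: 30
#' compounds, 3 docking poses per compound simulated in duplicate (6
#' independent simulations each), benzimidazole-like true parameters
#' (alpha 0.33, beta 0.12, gamma -13 kJ/mol at 300 K), interaction-energy
#' differences centred at (-45, -15) kJ/mol with realistic spread, and
#' 2 kJ/mol Gaussian observation noise on the observed free energies.
#'
#' @param n_compounds number of training compounds.
#' @param n_poses docking poses per compound.
#' @param replicates replicate MD runs per pose.
#' @param alpha,beta,gamma,temperature true generating LIE parameters.
#' @param dv_mean length-2 mean of the per-simulation `(dV_vdw, dV_ele)`
#'   distribution (kJ/mol).
#' @param dv_cov 2x2 covariance of the per-simulation differences.
#' @param noise_sd Gaussian observation noise on `dG_obs` (kJ/mol).
#' @param n_residues residues in the decomposition tables.
#' @param decomposition_rank rank of the decomposition factor model.
#' @param decomposition_noise_sd per-entry decomposition noise (kJ/mol).
#' @param fp_length fingerprint length in bits.
#' @param n_families structural families (fingerprint templates).
#' @param fp_flip_rate per-bit flip probability away from the family template.
#' @param seed global RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 30, n_poses = 3, replicates = 2,
                           alpha = 0.33, beta = 0.12, gamma = -13,
                           temperature = 300,
                           dv_mean = c(-45, -15),
                           dv_cov = matrix(c(60, 15, 15, 30), 2, 2),
                           noise_sd = 2,
                           n_residues = 20, decomposition_rank = 3,
                           decomposition_noise_sd = 0.5,
                           fp_length = 128, n_families = 3,
                           fp_flip_rate = 0.05,
                           seed = 1) {
  stopifnot(n_compounds >= 1, n_poses >= 1, replicates >= 1, noise_sd >= 0,
            n_residues >= 2, decomposition_rank >= 1,
            decomposition_rank <= n_residues - 1,
            fp_length >= 8, n_families >= 1, fp_flip_rate >= 0,
            fp_flip_rate <= 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_poses = as.integer(n_poses),
                 replicates = as.integer(replicates),
                 params = lie_parameters(alpha, beta, gamma, temperature),
                 dv_mean = dv_mean, dv_cov = dv_cov, noise_sd = noise_sd,
                 n_residues = as.integer(n_residues),
                 decomposition_rank = as.integer(decomposition_rank),
                 decomposition_noise_sd = decomposition_noise_sd,
                 fp_length = as.integer(fp_length),
                 n_families = as.integer(n_families),
                 fp_flip_rate = fp_flip_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic training set with known ground truth
#'
#' Per compound, per-simulation `(dV_vdw, dV_ele)` pairs are drawn from the
#' spec's bivariate Gaussian; the observed free energy is the full
#' Boltzmann-weighted forward model under the true parameters plus Gaussian
#' noise. Bound means are emitted as unbound + dV so that the energetics
#' reproduce the drawn differences exactly. Fingerprints and per-residue
#' decompositions consistent with the weighted totals are attached.
#'
#' @param spec a [synthetic_spec()].
#' @return List of [training_compound()] objects. Attribute `truth` holds
#'   the generating parameters, the noiseless weighted free energies and the
#'   weighted interaction totals per compound.
#' @export
generate_training_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_compounds
  nsim <- spec$n_poses * spec$replicates
  p <- spec$params

  draws <- with_local_seed(sub_seed(spec$seed, 1L), {
    lapply(seq_len(n), function(i) {
      dv <- MASS::mvrnorm(nsim, spec$dv_mean, spec$dv_cov)
      dv <- matrix(dv, ncol = 2L)
      list(unbound = c(stats::rnorm(1, -40, 5), stats::rnorm(1, -25, 5)),
           dv = dv,
           noise = stats::rnorm(1, 0, spec$noise_sd))
    })
  })

  dg_true <- numeric(n)
  totals <- matrix(0, n, 2L, dimnames = list(NULL, c("dv_vdw", "dv_ele")))
  compounds <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[[i]]
    dg_i <- per_simulation_dg(p, d$dv[, 1L], d$dv[, 2L])
    w <- boltzmann_weights(dg_i, p$temperature)
    dg_true[i] <- sum(w * dg_i)
    totals[i, ] <- c(sum(w * d$dv[, 1L]), sum(w * d$dv[, 2L]))
    bound <- data.frame(
      pose = rep(seq_len(spec$n_poses), each = spec$replicates),
      replicate = rep(seq_len(spec$replicates), times = spec$n_poses),
      mean_vdw = d$unbound[1L] + d$dv[, 1L],
      mean_ele = d$unbound[2L] + d$dv[, 2L])
    en <- compound_energetics(sprintf("cpd%03d", i), bound,
                              d$unbound[1L], d$unbound[2L])
    compounds[[i]] <- list(energetics = en,
                           dg_obs = dg_true[i] + d$noise)
  }

  fps <- generate_fingerprints(spec, n)
  dec_vdw <- generate_decompositions(spec, totals[, 1L], type_offset = 0L)
  dec_ele <- generate_decompositions(spec, totals[, 2L], type_offset = 1L)

  out <- lapply(seq_len(n), function(i) {
    training_compound(compounds[[i]]$energetics$compound_id,
                      compounds[[i]]$dg_obs,
                      compounds[[i]]$energetics,
                      fingerprint = fps[i, ],
                      decomposition_vdw = dec_vdw[i, ],
                      decomposition_ele = dec_ele[i, ])
  })
  attr(out, "truth") <- list(params = p, dg_true = dg_true, totals = totals)
  out
}

#' Generate per-residue decomposition matrices
#'
#' Low-rank factor model: each compound's decomposition is its total
#' interaction energy spread over a common residue profile, plus sum-zero
#' low-rank variation and sum-zero noise, so every row sums exactly to the
#' compound total for that energy type.
#'
#' @param spec a [synthetic_spec()].
#' @param totals per-compound total interaction energies (kJ/mol) the rows
#'   must sum to.
#' @param type_offset sub-seed offset distinguishing energy types.
#' @return Matrix `length(totals)` x `spec$n_residues`.
#' @export
generate_decompositions <- function(spec, totals, type_offset = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- length(totals)
  R <- spec$n_residues
  r_extra <- spec$decomposition_rank - 1L
  with_local_seed(sub_seed(spec$seed, 10L + type_offset), {
    w <- abs(stats::rnorm(R, 1, 0.5)) + 0.1
    w <- w / sum(w)                      # common residue profile, sums to 1
    D <- totals %*% t(w)
    if (r_extra > 0L) {
      # sum-zero orthonormal extra directions with decreasing score variance
      Q <- matrix(stats::rnorm(R * r_extra), R, r_extra)
      Q <- sweep(Q, 2L, colMeans(Q))     # column sums zero
      Q <- qr.Q(qr(Q))
      Q <- sweep(Q, 2L, colSums(Q) / R)  # re-zero after orthonormalisation
      sdev <- 6 / seq_len(r_extra)
      S <- matrix(stats::rnorm(n * r_extra), n, r_extra) %*% diag(sdev,
                                                                  r_extra)
      D <- D + S %*% t(Q)
    }
    if (spec$decomposition_noise_sd > 0) {
      E <- matrix(stats::rnorm(n * R, 0, spec$decomposition_noise_sd), n, R)
      E <- E - rowMeans(E)               # keep row sums exact
      D <- D + E
    }
    colnames(D) <- sprintf("res%02d", seq_len(R))
    D
  })
}

#' Generate family-structured fingerprints
#'
#' Each structural family has a random template bit pattern; compounds
#' inherit their family template with independent per-bit flips, so
#' within-family similarity exceeds between-family similarity in
#' expectation.
#'
#' @param spec a [synthetic_spec()].
#' @param n number of fingerprints (compounds), assigned to families
#'   round-robin.
#' @return 0/1 integer matrix `n` x `spec$fp_length` with attribute
#'   `families`.
#' @export
generate_fingerprints <- function(spec, n = spec$n_compounds) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(sub_seed(spec$seed, 20L), {
    templates <- matrix(stats::rbinom(spec$n_families * spec$fp_length, 1,
                                      0.3),
                        spec$n_families, spec$fp_length)
    fam <- rep_len(seq_len(spec$n_families), n)
    fp <- t(vapply(seq_len(n), function(i) {
      bits <- templates[fam[i], ]
      flips <- stats::rbinom(spec$fp_length, 1, spec$fp_flip_rate)
      out <- as.integer(xor(bits, flips))
      if (sum(out) == 0L) out[1L] <- 1L  # never emit an empty fingerprint
      out
    }, integer(spec$fp_length)))
    attr(fp, "families") <- fam
    fp
  })
}

#' Generate a synthetic docking-pose cloud
#'
#' `k_true` Gaussian clusters of conformations around shifted copies of a
#' random template structure; cluster centres are `separation` nm apart
#' along x and each pose is the centre plus isotropic noise of standard
#' deviation `spread` nm.
#'
#' @param n_poses total poses (assigned to clusters round-robin).
#' @param k_true number of underlying binding modes.
#' @param separation centre-to-centre distance (nm).
#' @param spread within-cluster coordinate standard deviation (nm).
#' @param n_atoms heavy atoms per pose.
#' @param seed RNG seed.
#' @return A [pose_set()] with attribute `true_assignments`.
#' @export
generate_pose_cloud <- function(n_poses, k_true = 2, separation = 1,
                                spread = 0.05, n_atoms = 10, seed = 1) {
  stopifnot(n_poses >= 1, k_true >= 1, separation >= 0, spread >= 0)
  with_local_seed(seed, {
    template <- matrix(stats::runif(n_atoms * 3), n_atoms, 3L)
    assign <- rep_len(seq_len(k_true), n_poses)
    poses <- lapply(seq_len(n_poses), function(i) {
      centre <- template
      centre[, 1L] <- centre[, 1L] + (assign[i] - 1L) * separation
      centre + matrix(stats::rnorm(n_atoms * 3, 0, spread), n_atoms, 3L)
    })
    ps <- pose_set("synthetic", poses)
    attr(ps, "true_assignments") <- assign
    ps
  })
}

#' Long-form energy table consistent with a synthetic training set
#'
#' Emits per-frame interaction-energy rows (10 ps cadence) whose
#' per-simulation means equal the record means of
#' [generate_training_set()] exactly: frame values are the mean plus a
#' sum-zero perturbation. Includes duplicated unbound reference runs.
#'
#' @param spec a [synthetic_spec()].
#' @param n_frames frames per simulation (default 100, i.e. 1 ns at 10 ps).
#' @param jitter_sd frame-to-frame fluctuation amplitude (kJ/mol).
#' @return data.frame in the canonical `read_energy_table()` schema.
#' @export
synthetic_energy_table <- function(spec, n_frames = 100, jitter_sd = 5) {
  training <- generate_training_set(spec)
  times <- seq_len(n_frames) * 10
  rows <- list()
  with_local_seed(sub_seed(spec$seed, 30L), {
    zero_sum <- function(sd) {
      e <- stats::rnorm(n_frames, 0, sd)
      e - mean(e)
    }
    for (tc in training) {
      en <- tc$energetics
      for (i in seq_len(nrow(en$bound))) {
        b <- en$bound[i, ]
        rows[[length(rows) + 1L]] <- data.frame(
          compound = en$compound_id, pose = b$pose, replicate = b$replicate,
          state = "bound", time_ps = times,
          v_vdw = b$mean_vdw + zero_sum(jitter_sd),
          v_ele = b$mean_ele + zero_sum(jitter_sd))
      }
      for (rep_i in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound = en$compound_id, pose = 0, replicate = rep_i,
          state = "unbound", time_ps = times,
          v_vdw = en$unbound[["mean_vdw"]] + zero_sum(jitter_sd),
          v_ele = en$unbound[["mean_ele"]] + zero_sum(jitter_sd))
      }
    }
  })
  do.call(rbind, rows)
}
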