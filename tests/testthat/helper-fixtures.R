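# Shared fixtures and independent oracles.

RT300 <- 0.0083145 * 300

# Brute-force oracle for the Boltzmann-weighted LIE prediction: literal
# per-simulation evaluation with plain exponentials, independent of the
# package implementation (no max-shift, scalar loops).
oracle_predict <- function(alpha, beta, gamma, temperature, dv) {
  n <- nrow(dv)
  dg_i <- numeric(n)
  for (i in seq_len(n)) dg_i[i] <- alpha * dv[i, 1] + beta * dv[i, 2] + gamma
  e <- numeric(n)
  for (i in seq_len(n)) e[i] <- exp(-dg_i[i] / (0.0083145 * temperature))
  w <- e / sum(e)
  alpha * sum(w * dv[, 1]) + beta * sum(w * dv[, 2]) + gamma
}

# compound_energetics whose delta interactions equal the given dv matrix
make_energetics <- function(dv, id = "q", unbound = c(-40, -25)) {
  dv <- matrix(dv, ncol = 2)
  bound <- data.frame(pose = seq_len(nrow(dv)), replicate = 1,
                      mean_vdw = unbound[1] + dv[, 1],
                      mean_ele = unbound[2] + dv[, 2])
  compound_energetics(id, bound, unbound[1], unbound[2])
}

# single-pose training compound lying exactly on a given linear model
make_linear_compound <- function(id, dv_vdw, dv_ele, alpha, beta, gamma,
                                 noise = 0) {
  en <- make_energetics(cbind(dv_vdw, dv_ele), id = id)
  training_compound(id, alpha * dv_vdw + beta * dv_ele + gamma + noise, en)
}

# bit vector of given length with 1s at the listed positions
bits <- function(positions, length = 8L) {
  v <- integer(length)
  v[positions] <- 1L
  v
}

# pose_set with an exactly prescribed PCA eigen-spectrum: orthonormal
# centred score directions (orthogonal polynomial contrasts) scaled so the
# coordinate covariance eigenvalues have the requested fractions
spectrum_poses <- function(fractions, n_poses = 6, n_atoms = 2) {
  stopifnot(length(fractions) <= min(n_poses - 1, 3 * n_atoms))
  P <- stats::contr.poly(n_poses)[, seq_along(fractions), drop = FALSE]
  X <- matrix(0, n_poses, 3 * n_atoms)
  for (j in seq_along(fractions))
    X[, j] <- P[, j] * sqrt(fractions[j] * (n_poses - 1))
  pose_set("spectrum", lapply(seq_len(n_poses), function(i)
    matrix(X[i, ], n_atoms, 3)))
}

# a frame-table row builder for interaction-profile tests
frame_atom <- function(frame, side, residue, atom, element, x, y, z,
                       donor = FALSE, acceptor = FALSE, hydrophobe = FALSE,
                       bonded_to = NA_character_) {
  data.frame(frame = frame, side = side, residue = residue, atom = atom,
             element = element, x = x, y = y, z = z, is_donor = donor,
             is_acceptor = acceptor, is_hydrophobe = hydrophobe,
             bonded_to = bonded_to, stringsAsFactors = FALSE)
}

# single-frame geometry: a ligand donor (with hydrogen) facing a protein
# residue acceptor at distance `d_da` nm, plus an optional apolar contact
hbond_frame <- function(frame = 1, d_da = 0.28, h_towards_acceptor = TRUE,
                        phob_dist = NULL) {
  h_x <- if (h_towards_acceptor) 0.1 else -0.1
  rows <- rbind(
    frame_atom(frame, "ligand", "LIG", "L_N", "N", 0, 0, 0, donor = TRUE),
    frame_atom(frame, "ligand", "LIG", "L_H", "H", h_x, 0, 0,
               bonded_to = "L_N"),
    frame_atom(frame, "protein", "Ser90", "P_O", "O", d_da, 0, 0,
               acceptor = TRUE))
  if (!is.null(phob_dist)) {
    rows <- rbind(rows,
      frame_atom(frame, "ligand", "LIG", "L_C", "C", 0, 1, 0,
                 hydrophobe = TRUE),
      frame_atom(frame, "protein", "Ile335", "P_C", "C", 0, 1 + phob_dist, 0,
                 hydrophobe = TRUE))
  }
  rows
}

# in-domain query built from a training compound plus targeted perturbations:
# each of pair / fingerprint / decomposition can be overridden independently
make_query <- function(base, pair = NULL, fingerprint = NULL,
                       decomposition_vdw = NULL, decomposition_ele = NULL,
                       id = "query") {
  en <- if (is.null(pair)) base$energetics
        else make_energetics(matrix(pair, ncol = 2), id = id)
  query_compound(id, en,
                 fingerprint = if (is.null(fingerprint)) base$fingerprint
                               else fingerprint,
                 decomposition_vdw = if (is.null(decomposition_vdw))
                   base$decomposition_vdw else decomposition_vdw,
                 decomposition_ele = if (is.null(decomposition_ele))
                   base$decomposition_ele else decomposition_ele)
}

# unit vector orthogonal to all retained loadings of a PCA reference
orthogonal_direction <- function(pca, seed = 99) {
  set.seed(seed)
  v <- rnorm(length(pca$center))
  if (pca$retained > 0)
    v <- v - drop(pca$loadings %*% crossprod(pca$loadings, v))
  v / sqrt(sum(v^2))
}

# index of the most central training compound under a fitted reference:
# smallest worst-case normalised distance across criteria 3-5 with a
# prediction nearest the middle of the training range
most_central_index <- function(training, params, ref) {
  n <- length(training)
  dg <- vapply(training, function(tc)
    lie_predict(params, tc$energetics)$dg_pred, numeric(1))
  mid <- mean(ref$dg_range)
  dg_score <- abs(dg - mid) / (diff(range(dg)) / 2)
  d3 <- vapply(seq_len(n), function(i) {
    pair <- weighted_interactions(params, training[[i]]$energetics)
    criterion_energy(pair, ref)$observed
  }, numeric(1)) / ref$mahalanobis_threshold
  dec_score <- function(pca, field) {
    vapply(seq_len(n), function(i) {
      r <- criterion_decomposition(training[[i]][[field]], pca)
      max(r$score_distance / pca$sd_threshold,
          r$orthogonal_distance / pca$od_threshold)
    }, numeric(1))
  }
  worst <- pmax(dg_score, d3,
                dec_score(ref$pca_vdw, "decomposition_vdw"),
                dec_score(ref$pca_ele, "decomposition_ele"))
  which.min(worst)
}
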