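# Five-criterion applicability-domain (AD) assessment of LIE predictions.
#
# A trained empirical model is only reliable near the chemical and
# interaction space spanned by its training compounds. Each prediction is
# checked against five criteria; every violation adds 1 to a confidence
# index (CI) ranging from 0 (no violation, high confidence) to 5 (all
# violated, low confidence):
#   1. the predicted free energy lies inside the range of calculated
#      training free energies (inclusive);
#   2. the best Tanimoto fingerprint similarity to any training compound is
#      strictly higher than the training-set cutoff (the lowest
#      best-to-any-other similarity among training compounds);
#   3. the Boltzmann-weighted (dV_vdw, dV_ele) pair falls within the
#      empirical 95th percentile of training Mahalanobis distances from the
#      training centroid;
#   4./5. the per-residue van der Waals / electrostatic energy
#      decompositions, projected onto the training PCA space, have score and
#      orthogonal distances within the empirical 95th percentiles of the
#      training distributions (inclusive at the threshold).

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` for 0/1 (or logical) bit vectors of equal length.
#'
#' @param a,b bit vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("fingerprints must have equal length")
  union <- sum(a | b)
  if (union == 0L) stop("Tanimoto similarity undefined for two empty fingerprints")
  sum(a & b) / union
}

#' Training-set Tanimoto similarity cutoff
#'
#' For each compound, the highest Tanimoto similarity to any other compound
#' in the set; the cutoff is the lowest of these best-neighbour similarities.
#' A query whose best similarity to the training set does not exceed this
#' cutoff is less similar to the training set than its least-typical member
#' is to the rest.
#'
#' @param fingerprints list of 0/1 bit vectors (>= 2).
#' @return The cutoff similarity.
#' @export
tanimoto_cutoff <- function(fingerprints) {
  n <- length(fingerprints)
  if (n < 2L) stop("cutoff requires at least 2 fingerprints")
  best <- vapply(seq_len(n), function(i) {
    max(vapply(setdiff(seq_len(n), i), function(j)
      tanimoto(fingerprints[[i]], fingerprints[[j]]), numeric(1)))
  }, numeric(1))
  min(best)
}

#' Component retention by the 5%-increment rule
#'
#' Scanning components in decreasing-eigenvalue order, a component is
#' retained while it adds at least `min_increment` of the total explained
#' variance; the scan stops at the first component below the increment. At
#' least one component is always retained.
#'
#' @param fractions explained-variance fractions in decreasing order.
#' @param min_increment minimum additional explained-variance fraction
#'   (default 0.05).
#' @return Number of retained components.
#' @export
retain_components <- function(fractions, min_increment = 0.05) {
  stopifnot(length(fractions) >= 1L)
  r <- 1L
  while (r < length(fractions) && fractions[r + 1L] >= min_increment)
    r <- r + 1L
  r
}

# Mahalanobis reference for the 2-D interaction-energy descriptor.
# Covariance is regularised by +1e-8 I when near-singular.

#' Interaction-energy domain of a training set
#'
#' Centroid, (regularised) covariance, per-point Mahalanobis distances and
#' the empirical percentile threshold for a set of 2-D interaction-energy
#' descriptors.
#'
#' @param points numeric matrix (n x 2) of Boltzmann-weighted
#'   `(dV_vdw, dV_ele)` pairs.
#' @param percentile empirical percentile defining the threshold
#'   (default 0.95).
#' @return List with `centroid`, `covariance`, `distances`, `threshold`.
#' @export
energy_domain <- function(points, percentile = 0.95) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 3L)
  centroid <- colMeans(points)
  covm <- stats::cov(points)
  ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(abs(ev), 1))
    covm <- covm + diag(1e-8, 2L)
  d <- sqrt(stats::mahalanobis(points, centroid, covm))
  list(centroid = centroid, covariance = covm, distances = d,
       threshold = unname(stats::quantile(d, percentile, names = FALSE)))
}

# PCA reference (center, loadings, eigenvalues, retained count, empirical
# score- and orthogonal-distance thresholds) for one decomposition type.
pca_reference <- function(X, percentile = 0.95, min_increment = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3L)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  totvar <- sum(Xc^2) / (n - 1)
  if (totvar < 1e-12) {
    return(list(center = center, loadings = matrix(0, ncol(X), 0L),
                eigenvalues = numeric(0), retained = 0L,
                sd_threshold = 0, od_threshold = 0,
                sd_training = rep(0, n), od_training = rep(0, n)))
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  lambda <- pr$sdev^2
  fracs <- lambda / sum(lambda)
  r <- retain_components(fracs, min_increment)
  loadings <- pr$rotation[, seq_len(r), drop = FALSE]
  lam_r <- pmax(lambda[seq_len(r)], 1e-12)
  scores <- Xc %*% loadings
  sd_tr <- sqrt(rowSums(sweep(scores^2, 2L, lam_r, "/")))
  resid <- Xc - scores %*% t(loadings)
  od_tr <- sqrt(rowSums(resid^2))
  list(center = center, loadings = loadings, eigenvalues = lam_r,
       retained = r,
       sd_threshold = unname(stats::quantile(sd_tr, percentile, names = FALSE)),
       od_threshold = unname(stats::quantile(od_tr, percentile, names = FALSE)),
       sd_training = sd_tr, od_training = od_tr)
}

#' Build the applicability-domain reference from a training set
#'
#' Freezes everything the five criteria need: the range of calculated
#' training free energies, the Tanimoto cutoff (lowest best-to-any-other
#' similarity among training compounds), the centroid/covariance/threshold of
#' the Boltzmann-weighted interaction-energy pairs, and a PCA reference for
#' each per-residue decomposition type.
#'
#' @param training list of [training_compound()] objects carrying
#'   fingerprints and both decomposition vectors; n >= 5.
#' @param params fitted [lie_parameters()].
#' @param percentile empirical percentile for criteria 3-5 thresholds
#'   (default 0.95).
#' @param min_increment explained-variance increment for PCA component
#'   retention (default 0.05).
#' @return An object of class `ad_reference`.
#' @export
build_ad_reference <- function(training, params, percentile = 0.95,
                               min_increment = 0.05) {
  stopifnot(is.list(training), inherits(params, "lie_parameters"))
  n <- length(training)
  if (n < 5L) stop("AD reference requires at least 5 training compounds")
  ids <- vapply(training, function(tc) tc$compound_id, character(1))
  missing_fp <- ids[vapply(training, function(tc) is.null(tc$fingerprint),
                           logical(1))]
  if (length(missing_fp))
    stop("training compounds without fingerprints: ",
         paste(missing_fp, collapse = ", "))
  missing_dec <- ids[vapply(training, function(tc)
    is.null(tc$decomposition_vdw) || is.null(tc$decomposition_ele),
    logical(1))]
  if (length(missing_dec))
    stop("training compounds without decompositions: ",
         paste(missing_dec, collapse = ", "))
  nres <- unique(vapply(training, function(tc)
    length(tc$decomposition_vdw), integer(1)))
  nres2 <- unique(vapply(training, function(tc)
    length(tc$decomposition_ele), integer(1)))
  if (length(nres) != 1L || length(nres2) != 1L || nres != nres2)
    stop("all decomposition vectors must share one residue index")

  # criterion 1: range of calculated free energies of the training compounds
  dg_calc <- vapply(training, function(tc)
    lie_predict(params, tc$energetics)$dg_pred, numeric(1))

  # criterion 2: lowest best-to-any-other Tanimoto among training compounds
  fps <- lapply(training, function(tc) tc$fingerprint)
  ts_cutoff <- tanimoto_cutoff(fps)

  # criterion 3: Mahalanobis domain of the weighted interaction-energy pairs
  pairs <- t(vapply(training, function(tc)
    weighted_interactions(params, tc$energetics), numeric(2)))
  colnames(pairs) <- c("dv_vdw", "dv_ele")
  energy <- energy_domain(pairs, percentile)

  # criteria 4-5: PCA references per decomposition type
  Xv <- t(vapply(training, function(tc) as.numeric(tc$decomposition_vdw),
                 numeric(nres)))
  Xe <- t(vapply(training, function(tc) as.numeric(tc$decomposition_ele),
                 numeric(nres)))

  structure(list(
    n_training = n,
    compound_ids = ids,
    dg_range = c(min = min(dg_calc), max = max(dg_calc)),
    dg_calc = dg_calc,
    ts_cutoff = ts_cutoff,
    fingerprints = fps,
    energy_centroid = energy$centroid,
    energy_covariance = energy$covariance,
    mahalanobis_threshold = energy$threshold,
    energy_pairs = pairs,
    pca_vdw = pca_reference(Xv, percentile, min_increment),
    pca_ele = pca_reference(Xe, percentile, min_increment),
    percentile = percentile,
    min_increment = min_increment
  ), class = "ad_reference")
}

#' @export
print.ad_reference <- function(x, ...) {
  cat(sprintf("<ad_reference> n = %d training compounds\n", x$n_training))
  cat(sprintf("  dG range [%.2f, %.2f] kJ/mol; Tanimoto cutoff %.3f\n",
              x$dg_range[["min"]], x$dg_range[["max"]], x$ts_cutoff))
  cat(sprintf("  Mahalanobis threshold %.3f; PCA components vdw %d / ele %d\n",
              x$mahalanobis_threshold, x$pca_vdw$retained, x$pca_ele$retained))
  invisible(x)
}

#' Criterion 1: prediction-range check
#'
#' Violated (flag 1) when the predicted free energy falls outside the
#' inclusive `[min, max]` range of calculated training free energies.
#'
#' @param dg_pred predicted free energy (kJ/mol).
#' @param reference an [build_ad_reference()] result.
#' @return List with `flag` (0/1), `observed`, `lower`, `upper`.
#' @export
criterion_range <- function(dg_pred, reference) {
  lo <- reference$dg_range[["min"]]
  hi <- reference$dg_range[["max"]]
  list(flag = as.integer(dg_pred < lo || dg_pred > hi),
       observed = dg_pred, lower = lo, upper = hi)
}

#' Criterion 2: fingerprint-similarity check
#'
#' Violated (flag 1) unless the best Tanimoto similarity of the query to any
#' training compound is strictly higher than the training cutoff.
#'
#' @param fingerprint query bit vector.
#' @param reference an [build_ad_reference()] result.
#' @return List with `flag`, `observed` (best similarity), `cutoff`.
#' @export
criterion_similarity <- function(fingerprint, reference) {
  if (is.null(fingerprint)) stop("query has no fingerprint")
  best <- max(vapply(reference$fingerprints, function(fp)
    tanimoto(fingerprint, fp), numeric(1)))
  list(flag = as.integer(!(best > reference$ts_cutoff)),
       observed = best, cutoff = reference$ts_cutoff)
}

#' Criterion 3: interaction-energy domain check
#'
#' Violated (flag 1) when the Mahalanobis distance of the query's weighted
#' `(dV_vdw, dV_ele)` pair from the training centroid exceeds the empirical
#' percentile threshold (inclusive at the threshold).
#'
#' @param pair named vector `c(dv_vdw =, dv_ele =)` (kJ/mol).
#' @param reference an [build_ad_reference()] result.
#' @return List with `flag`, `observed` (distance), `threshold`.
#' @export
criterion_energy <- function(pair, reference) {
  d <- sqrt(stats::mahalanobis(matrix(as.numeric(pair), 1L),
                               reference$energy_centroid,
                               reference$energy_covariance))
  list(flag = as.integer(d > reference$mahalanobis_threshold),
       observed = unname(d), threshold = reference$mahalanobis_threshold)
}

#' Criteria 4/5: decomposition-projection check
#'
#' The query's per-residue decomposition is centred by the training mean and
#' projected onto the retained principal components. Violated (flag 1) when
#' either the score distance (Mahalanobis in score space, eigenvalue-scaled)
#' or the orthogonal distance (norm of the projection residual) exceeds its
#' empirical percentile threshold.
#'
#' @param decomposition per-residue energy vector (kJ/mol) on the training
#'   residue index.
#' @param pca one of `reference$pca_vdw` / `reference$pca_ele`.
#' @return List with `flag`, `score_distance`, `orthogonal_distance`,
#'   `sd_threshold`, `od_threshold`.
#' @export
criterion_decomposition <- function(decomposition, pca) {
  if (is.null(decomposition)) stop("query has no decomposition vector")
  x <- as.numeric(decomposition)
  if (length(x) != length(pca$center))
    stop("decomposition length does not match the training residue index")
  xc <- x - pca$center
  if (pca$retained == 0L) {
    sdist <- 0
    odist <- sqrt(sum(xc^2))
  } else {
    sc <- drop(crossprod(pca$loadings, xc))
    sdist <- sqrt(sum(sc^2 / pca$eigenvalues))
    odist <- sqrt(sum((xc - drop(pca$loadings %*% sc))^2))
  }
  list(flag = as.integer(sdist > pca$sd_threshold || odist > pca$od_threshold),
       score_distance = sdist, orthogonal_distance = odist,
       sd_threshold = pca$sd_threshold, od_threshold = pca$od_threshold)
}

#' Confidence index from per-criterion flags
#'
#' @param flags integer vector of 5 violation flags (0/1), ordered
#'   range / similarity / energy / decomposition-vdw / decomposition-ele.
#' @param diagnostics optional per-criterion diagnostics kept in the report.
#' @return An object of class `confidence_report` with `flags` and
#'   `ci_total` = sum of flags (0-5).
#' @export
confidence_index <- function(flags, diagnostics = NULL) {
  flags <- as.integer(flags)
  if (length(flags) != 5L || any(is.na(flags)) || any(!flags %in% c(0L, 1L)))
    stop("flags must be five 0/1 values")
  names(flags) <- c("range", "similarity", "energy", "decomposition_vdw",
                    "decomposition_ele")
  structure(list(flags = flags, ci_total = sum(flags),
                 diagnostics = diagnostics),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("<confidence_report> CI = %d/5 (violated: %s)\n", x$ci_total,
              if (x$ci_total == 0L) "none"
              else paste(names(x$flags)[x$flags == 1L], collapse = ", ")))
  invisible(x)
}

#' Query compound for AD assessment
#'
#' Like [training_compound()] but without an observed affinity.
#'
#' @inheritParams training_compound
#' @return An object of class `query_compound`.
#' @export
query_compound <- function(compound_id, energetics, fingerprint = NULL,
                           decomposition_vdw = NULL,
                           decomposition_ele = NULL) {
  stopifnot(inherits(energetics, "compound_energetics"))
  if (!is.null(fingerprint)) {
    fingerprint <- as.integer(fingerprint)
    if (any(is.na(fingerprint)) || any(!fingerprint %in% c(0L, 1L)))
      stop("fingerprint must be a 0/1 bit vector")
  }
  structure(list(compound_id = as.character(compound_id),
                 energetics = energetics, fingerprint = fingerprint,
                 decomposition_vdw = decomposition_vdw,
                 decomposition_ele = decomposition_ele),
            class = "query_compound")
}

#' Assess the applicability domain of a prediction
#'
#' Evaluates all five criteria for a query compound against a frozen
#' reference and sums the violation flags into the confidence index.
#'
#' @param reference an [build_ad_reference()] result.
#' @param params the fitted [lie_parameters()] the reference was built with.
#' @param query a [query_compound()] or [training_compound()] carrying
#'   energetics, a fingerprint and both decomposition vectors.
#' @return A `confidence_report` whose `diagnostics` data.frame lists, per
#'   criterion, the observed value, the threshold and the flag.
#' @export
assess_ad <- function(reference, params, query) {
  stopifnot(inherits(reference, "ad_reference"),
            inherits(params, "lie_parameters"))
  if (!inherits(query, c("query_compound", "training_compound")))
    stop("query must be a query_compound or training_compound")
  pred <- lie_predict(params, query$energetics)
  pair <- weighted_interactions(params, query$energetics)
  c1 <- criterion_range(pred$dg_pred, reference)
  c2 <- criterion_similarity(query$fingerprint, reference)
  c3 <- criterion_energy(pair, reference)
  c4 <- criterion_decomposition(query$decomposition_vdw, reference$pca_vdw)
  c5 <- criterion_decomposition(query$decomposition_ele, reference$pca_ele)
  diagnostics <- data.frame(
    criterion = c("range", "similarity", "energy", "decomposition_vdw",
                  "decomposition_ele"),
    observed = c(c1$observed, c2$observed, c3$observed,
                 max(c4$score_distance / max(c4$sd_threshold, 1e-300),
                     c4$orthogonal_distance / max(c4$od_threshold, 1e-300)),
                 max(c5$score_distance / max(c5$sd_threshold, 1e-300),
                     c5$orthogonal_distance / max(c5$od_threshold, 1e-300))),
    threshold = c(NA, c2$cutoff, c3$threshold, 1, 1),
    flag = c(c1$flag, c2$flag, c3$flag, c4$flag, c5$flag),
    stringsAsFactors = FALSE)
  confidence_index(diagnostics$flag, diagnostics)
}
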