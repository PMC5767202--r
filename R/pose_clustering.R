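# Representative docking-pose selection: PCA on heavy-atom coordinates,
# k-means clustering in score space, medoid extraction.
#
# Docking typically returns tens of poses per ligand; only a few distinct
# binding modes are worth simulating. Poses (which share the receptor frame,
# so raw coordinates are comparable) are mean-centred and decomposed by PCA;
# components are retained by the 5%-explained-variance increment rule.
# k-means then grows k while each extra cluster adds at least 5 percentage
# points of between-cluster explained variance, and the medoid of each
# cluster (the member pose minimising the summed distance to its cluster in
# score space, never a synthetic centroid) is returned as the representative
# binding pose — typically 2-3 per ligand.

#' Set of docking poses for one compound
#'
#' @param compound_id identifier.
#' @param poses list of numeric matrices (n_atoms x 3, coordinates in nm),
#'   all with identical atom count and ordering (heavy atoms only).
#' @return An object of class `pose_set`.
#' @export
pose_set <- function(compound_id, poses) {
  stopifnot(is.list(poses), length(poses) >= 1L)
  poses <- lapply(poses, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("each pose must be an n_atoms x 3 matrix")
    if (any(!is.finite(p))) stop("pose coordinates must be finite")
    unname(p)
  })
  natoms <- unique(vapply(poses, nrow, integer(1)))
  if (length(natoms) != 1L)
    stop("all poses must have the same atom count and ordering")
  structure(list(compound_id = as.character(compound_id), poses = poses,
                 n_atoms = natoms),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %s: %d pose(s), %d heavy atom(s)\n",
              x$compound_id, length(x$poses), x$n_atoms))
  invisible(x)
}

# run code under a local RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' PCA of a pose set
#'
#' Flattens each pose into a 3*n_atoms coordinate vector, mean-centres the
#' pose-by-coordinate matrix and decomposes it. Components are retained by
#' the 5%-explained-variance increment rule ([retain_components()]). A set
#' of identical poses carries no variance: `retained_components` is 0 and
#' the result is marked degenerate.
#'
#' @param poses a [pose_set()] with at least 2 poses.
#' @param min_increment explained-variance increment (default 0.05).
#' @return List with `scores` (poses x retained components),
#'   `retained_components`, `explained` (variance fractions) and `degenerate`.
#' @export
pose_pca <- function(poses, min_increment = 0.05) {
  stopifnot(inherits(poses, "pose_set"))
  n <- length(poses$poses)
  if (n < 2L) stop("pose_pca needs at least 2 poses")
  X <- t(vapply(poses$poses, as.numeric, numeric(3L * poses$n_atoms)))
  Xc <- sweep(X, 2L, colMeans(X))
  if (sum(Xc^2) < 1e-20) {
    return(list(scores = matrix(0, n, 0L), retained_components = 0L,
                explained = numeric(0), degenerate = TRUE))
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  lambda <- pr$sdev^2
  lambda <- lambda[lambda > 1e-12 * max(lambda)]
  fracs <- lambda / sum(lambda)
  r <- retain_components(fracs, min_increment)
  list(scores = pr$x[, seq_len(r), drop = FALSE], retained_components = r,
       explained = fracs, total_ss = sum(Xc^2), degenerate = FALSE)
}

#' Choose k and cluster pose PCA scores
#'
#' k grows from 1 while an additional k-means cluster raises the explained
#' fraction of the pose variance by at least `min_increment` (5 percentage
#' points by default); the scan stops at the first failure. The explained
#' fraction is the between-cluster sum of squares in score space relative to
#' the total coordinate-space variance of the poses (so variance discarded
#' by component retention still counts against a split, and a structureless
#' cloud does not keep earning clusters from its score subspace alone).
#' k-means is run with a fixed seed and multiple restarts; the medoid of
#' each cluster is its member with the smallest summed Euclidean distance to
#' the other members (ties broken by lowest pose index).
#'
#' @param scores the [pose_pca()] result (preferred; carries the total
#'   coordinate variance) or a bare score matrix, in which case the score
#'   variance is the denominator.
#' @param min_increment explained-variance-fraction increment.
#' @param seed RNG seed for k-means restarts (default 42).
#' @param nstart k-means restarts (default 10).
#' @return An object of class `cluster_result`: `k`, `assignments`,
#'   `medoid_indices`, `explained_fraction`.
#' @export
select_k_and_cluster <- function(scores, min_increment = 0.05, seed = 42,
                                 nstart = 10) {
  total_ss <- NULL
  if (is.list(scores) && !is.null(scores$scores)) {
    if (isTRUE(scores$degenerate)) {
      n <- nrow(scores$scores)
      return(structure(list(k = 1L, assignments = rep(1L, n),
                            medoid_indices = 1L, explained_fraction = 0),
                       class = "cluster_result"))
    }
    total_ss <- scores$total_ss
    scores <- scores$scores
  }
  scores <- as.matrix(scores)
  if (is.null(total_ss)) total_ss <- sum(sweep(scores, 2L,
                                               colMeans(scores))^2)
  n <- nrow(scores)
  if (n == 1L)
    return(structure(list(k = 1L, assignments = 1L, medoid_indices = 1L,
                          explained_fraction = 0),
                     class = "cluster_result"))
  n_distinct <- nrow(unique(scores))
  best <- list(k = 1L, assignments = rep(1L, n), frac = 0)
  frac_prev <- 0
  k <- 1L
  while (k < n_distinct) {
    k_try <- k + 1L
    km <- with_local_seed(seed + k_try, suppressWarnings(
      stats::kmeans(scores, centers = k_try, nstart = nstart,
                    iter.max = 100L)))
    frac <- km$betweenss / total_ss
    if (frac - frac_prev >= min_increment) {
      best <- list(k = k_try, assignments = as.integer(km$cluster),
                   frac = frac)
      frac_prev <- frac
      k <- k_try
    } else break
  }
  medoids <- vapply(seq_len(best$k), function(cl) {
    members <- which(best$assignments == cl)
    if (length(members) == 1L) return(members)
    d <- as.matrix(stats::dist(scores[members, , drop = FALSE]))
    members[which.min(rowSums(d))]
  }, integer(1))
  structure(list(k = best$k, assignments = best$assignments,
                 medoid_indices = sort(medoids),
                 explained_fraction = best$frac),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, medoid pose(s): %s (between-cluster fraction %.2f)\n",
              x$k, paste(x$medoid_indices, collapse = ", "),
              x$explained_fraction))
  invisible(x)
}

#' Representative docking poses
#'
#' End-to-end pose selection: PCA, cluster-count selection, k-means, medoid
#' extraction. Returns the medoid conformations in the original coordinates.
#'
#' @param poses a [pose_set()].
#' @param min_increment 5%-rule increment for components and clusters.
#' @param seed k-means seed.
#' @return List of pose matrices (the medoids), with attributes `indices`
#'   and `clustering` (the `cluster_result`).
#' @export
representative_poses <- function(poses, min_increment = 0.05, seed = 42) {
  stopifnot(inherits(poses, "pose_set"))
  if (length(poses$poses) == 1L) {
    out <- poses$poses[1L]
    attr(out, "indices") <- 1L
    attr(out, "clustering") <- structure(
      list(k = 1L, assignments = 1L, medoid_indices = 1L,
           explained_fraction = 0), class = "cluster_result")
    return(out)
  }
  pca <- pose_pca(poses, min_increment)
  cl <- select_k_and_cluster(pca, min_increment = min_increment, seed = seed)
  out <- poses$poses[cl$medoid_indices]
  attr(out, "indices") <- cl$medoid_indices
  attr(out, "clustering") <- cl
  out
}

#' Read docking poses from a multi-model PDB file
#'
#' Each MODEL block is one pose; hydrogens are discarded. Requires the
#' `bio3d` package.
#'
#' @param path PDB file path.
#' @param compound_id identifier for the returned set.
#' @return A [pose_set()]; coordinates converted from Angstrom to nm.
#' @export
read_poses_pdb <- function(path, compound_id = basename(path)) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB pose files requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  elety <- pdb$atom$elesy
  if (is.null(elety)) elety <- sub("^[0-9]*", "", substr(pdb$atom$elety, 1, 1))
  heavy <- !(toupper(trimws(elety)) %in% c("H", "D"))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  idx <- which(heavy)
  poses <- lapply(seq_len(nrow(xyz)), function(m) {
    coords <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    coords[idx, , drop = FALSE] / 10  # Angstrom -> nm
  })
  pose_set(compound_id, poses)
}

#' Read docking poses from a multi-record SDF file
#'
#' Each record is one pose of the same compound; hydrogens are discarded.
#' Requires the `ChemmineR` package.
#'
#' @inheritParams read_poses_pdb
#' @return A [pose_set()]; SDF coordinates (Angstrom) converted to nm.
#' @export
read_poses_sdf <- function(path, compound_id = basename(path)) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF pose files requires the ChemmineR package")
  sdf <- ChemmineR::read.SDFset(path)
  poses <- lapply(seq_along(sdf), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    elem <- gsub("_.*$", "", rownames(ab))
    heavy <- toupper(elem) != "H"
    unname(as.matrix(ab[heavy, 1:3, drop = FALSE])) / 10
  })
  pose_set(compound_id, poses)
}
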