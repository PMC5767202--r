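# Explicit (de)serialisation of the AD reference for the JSON model file.
# Matrices are stored flattened with dimensions so the round-trip is exact
# regardless of JSON array simplification.

mat_to_list <- function(m) list(data = as.numeric(m), nrow = nrow(m),
                                ncol = ncol(m))

mat_from_list <- function(l) matrix(as.numeric(l$data), nrow = l$nrow,
                                    ncol = l$ncol)

pca_to_list <- function(p) {
  list(center = as.numeric(p$center), loadings = mat_to_list(p$loadings),
       eigenvalues = as.numeric(p$eigenvalues), retained = p$retained,
       sd_threshold = p$sd_threshold, od_threshold = p$od_threshold,
       sd_training = as.numeric(p$sd_training),
       od_training = as.numeric(p$od_training))
}

pca_from_list <- function(l) {
  list(center = as.numeric(l$center), loadings = mat_from_list(l$loadings),
       eigenvalues = as.numeric(l$eigenvalues),
       retained = as.integer(l$retained),
       sd_threshold = as.numeric(l$sd_threshold),
       od_threshold = as.numeric(l$od_threshold),
       sd_training = as.numeric(l$sd_training),
       od_training = as.numeric(l$od_training))
}

ad_reference_to_list <- function(ref) {
  stopifnot(inherits(ref, "ad_reference"))
  list(n_training = ref$n_training,
       compound_ids = ref$compound_ids,
       dg_range = as.numeric(ref$dg_range),
       dg_calc = as.numeric(ref$dg_calc),
       ts_cutoff = ref$ts_cutoff,
       fingerprints = lapply(ref$fingerprints, as.integer),
       energy_centroid = as.numeric(ref$energy_centroid),
       energy_covariance = mat_to_list(ref$energy_covariance),
       mahalanobis_threshold = ref$mahalanobis_threshold,
       energy_pairs = mat_to_list(ref$energy_pairs),
       pca_vdw = pca_to_list(ref$pca_vdw),
       pca_ele = pca_to_list(ref$pca_ele),
       percentile = ref$percentile,
       min_increment = ref$min_increment)
}

ad_reference_from_list <- function(l) {
  pairs <- mat_from_list(l$energy_pairs)
  colnames(pairs) <- c("dv_vdw", "dv_ele")
  centroid <- as.numeric(l$energy_centroid)
  names(centroid) <- c("dv_vdw", "dv_ele")
  dg_range <- as.numeric(l$dg_range)
  names(dg_range) <- c("min", "max")
  fps <- l$fingerprints
  if (is.matrix(fps)) fps <- lapply(seq_len(nrow(fps)), function(i) fps[i, ])
  structure(list(
    n_training = as.integer(l$n_training),
    compound_ids = as.character(l$compound_ids),
    dg_range = dg_range,
    dg_calc = as.numeric(l$dg_calc),
    ts_cutoff = as.numeric(l$ts_cutoff),
    fingerprints = lapply(fps, as.integer),
    energy_centroid = centroid,
    energy_covariance = mat_from_list(l$energy_covariance),
    mahalanobis_threshold = as.numeric(l$mahalanobis_threshold),
    energy_pairs = pairs,
    pca_vdw = pca_from_list(l$pca_vdw),
    pca_ele = pca_from_list(l$pca_ele),
    percentile = as.numeric(l$percentile),
    min_increment = as.numeric(l$min_increment)
  ), class = "ad_reference")
}
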