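# Reference training set shared by the AD tests
ad_fixture <- local({
  spec <- synthetic_spec(n_compounds = 30, seed = 17)
  training <- generate_training_set(spec)
  model <- calibrate_lie(training, tol = 1e-8)
  ref <- build_ad_reference(training, model$parameters)
  list(training = training, params = model$parameters, ref = ref)
})

test_that("Tanimoto similarity is intersection over union", {
  expect_equal(tanimoto(bits(1:3), bits(1:3)), 1)
  expect_equal(tanimoto(bits(1:3), bits(4:6)), 0)
  expect_equal(tanimoto(bits(c(1, 2, 3)), bits(c(1, 2, 4))), 0.5)
  expect_error(tanimoto(bits(1), bits(1, 4)), "equal length")
  expect_error(tanimoto(integer(8), integer(8)), "undefined")
})

test_that("the training cutoff is the lowest best-neighbour similarity", {
  # A={1,2,3}, B={1,2,4}, C={1,5,6}: TS(A,B)=0.5, TS(A,C)=TS(B,C)=0.2;
  # best-neighbour similarities (0.5, 0.5, 0.2) -> cutoff 0.2
  fps <- list(bits(c(1, 2, 3)), bits(c(1, 2, 4)), bits(c(1, 5, 6)))
  expect_equal(tanimoto(fps[[1]], fps[[3]]), 0.2)
  expect_equal(tanimoto_cutoff(fps), 0.2)
  # duplicating a compound cannot lower anyone's best neighbour
  expect_equal(tanimoto_cutoff(c(fps, fps[1])), 0.2)
})

test_that("range criterion is inclusive at both boundaries", {
  ref <- ad_fixture$ref
  lo <- ref$dg_range[["min"]]; hi <- ref$dg_range[["max"]]
  expect_equal(criterion_range((lo + hi) / 2, ref)$flag, 0L)
  expect_equal(criterion_range(lo, ref)$flag, 0L)
  expect_equal(criterion_range(hi, ref)$flag, 0L)
  expect_equal(criterion_range(lo - 0.1, ref)$flag, 1L)
  expect_equal(criterion_range(hi + 0.1, ref)$flag, 1L)
})

test_that("similarity criterion is strict at the cutoff", {
  ref <- ad_fixture$ref
  # identical to a training compound: similarity 1 > cutoff
  expect_equal(criterion_similarity(ref$fingerprints[[1]], ref)$flag, 0L)
  # disjoint from every training compound: similarity 0
  used <- Reduce(`|`, lapply(ref$fingerprints, as.logical))
  expect_true(any(!used))  # some bits are unused by the whole training set
  novel <- as.integer(!used)
  expect_equal(criterion_similarity(novel, ref)$flag, 1L)
  # a best similarity exactly at the cutoff violates ("higher than")
  fps <- list(bits(c(1, 2, 3)), bits(c(1, 2, 4)), bits(c(5, 6, 7)),
              bits(c(5, 6, 8)))
  fake <- ad_fixture$ref
  fake$fingerprints <- fps
  fake$ts_cutoff <- tanimoto_cutoff(fps)
  expect_equal(fake$ts_cutoff, 0.5)
  q <- bits(c(1, 2, 5))  # best TS is 1/2, exactly the cutoff
  best <- max(vapply(fps, function(f) tanimoto(q, f), numeric(1)))
  expect_equal(best, fake$ts_cutoff)
  expect_equal(criterion_similarity(q, fake)$flag, 1L)
})

test_that("energy criterion is a Mahalanobis ellipse test", {
  ref <- ad_fixture$ref
  at_centre <- criterion_energy(ref$energy_centroid, ref)
  expect_equal(at_centre$observed, 0)
  expect_equal(at_centre$flag, 0L)
  far <- ref$energy_centroid + 10 * ref$mahalanobis_threshold *
    sqrt(diag(ref$energy_covariance))
  expect_equal(criterion_energy(far, ref)$flag, 1L)
  # identity covariance: Mahalanobis reduces to Euclidean distance
  fake <- ref
  fake$energy_centroid <- c(dv_vdw = 0, dv_ele = 0)
  fake$energy_covariance <- diag(2)
  fake$mahalanobis_threshold <- 4.9
  r <- criterion_energy(c(3, 4), fake)
  expect_equal(r$observed, 5)
  expect_equal(r$flag, 1L)
  fake$mahalanobis_threshold <- 5  # inclusive at the threshold
  expect_equal(criterion_energy(c(3, 4), fake)$flag, 0L)
})

test_that("the empirical 95th-percentile threshold keeps ceiling(0.95 n) points", {
  set.seed(2)
  pts <- MASS::mvrnorm(2000, c(-45, -15), matrix(c(60, 15, 15, 30), 2))
  dom <- energy_domain(pts, percentile = 0.95)
  expect_equal(sum(dom$distances <= dom$threshold), ceiling(0.95 * 2000))
})

test_that("decomposition criterion separates score and orthogonal violations", {
  ref <- ad_fixture$ref
  pca <- ref$pca_vdw
  # query at the training mean: both distances zero
  at_mean <- criterion_decomposition(pca$center, pca)
  expect_equal(at_mean$score_distance, 0)
  expect_equal(at_mean$orthogonal_distance, 0)
  expect_equal(at_mean$flag, 0L)
  # large perturbation orthogonal to the retained loadings: score distance
  # stays zero but the orthogonal distance blows up
  v <- orthogonal_direction(pca)
  q <- pca$center + 50 * pca$od_threshold * v
  r <- criterion_decomposition(q, pca)
  expect_lt(r$score_distance, 1e-6)
  expect_gt(r$orthogonal_distance, pca$od_threshold)
  expect_equal(r$flag, 1L)
  # in-plane excursion: score distance violation with zero orthogonal part
  u <- pca$loadings[, 1]
  q2 <- pca$center + 50 * sqrt(pca$eigenvalues[1]) * u
  r2 <- criterion_decomposition(q2, pca)
  expect_gt(r2$score_distance, pca$sd_threshold)
  expect_equal(r2$flag, 1L)
  expect_error(criterion_decomposition(1:3, pca), "residue index")
})

test_that("confidence index sums violation flags and is monotone", {
  expect_equal(confidence_index(c(0, 0, 0, 0, 0))$ci_total, 0L)
  expect_equal(confidence_index(c(1, 1, 1, 1, 1))$ci_total, 5L)
  expect_equal(confidence_index(c(1, 0, 1, 0, 0))$ci_total, 2L)
  # flipping any flag 0 -> 1 raises the total by exactly 1
  set.seed(1)
  for (i in 1:20) {
    flags <- rbinom(5, 1, 0.5)
    zero <- which(flags == 0L)
    if (!length(zero)) next
    j <- zero[sample.int(length(zero), 1)]
    flipped <- flags; flipped[j] <- 1L
    expect_equal(confidence_index(flipped)$ci_total,
                 confidence_index(flags)$ci_total + 1L)
  }
  expect_error(confidence_index(c(2, 0, 0, 0, 0)), "0/1")
  expect_error(confidence_index(c(1, 0, 0)), "0/1")
})

test_that("reference construction validates its inputs", {
  training <- ad_fixture$training
  expect_error(build_ad_reference(training[1:4], ad_fixture$params),
               "at least 5")
  nofp <- training
  nofp[[2]]$fingerprint <- NULL
  expect_error(build_ad_reference(nofp, ad_fixture$params),
               "without fingerprints: cpd002")
  nodec <- training
  nodec[[3]]$decomposition_vdw <- NULL
  expect_error(build_ad_reference(nodec, ad_fixture$params),
               "without decompositions: cpd003")
  # degenerate training set: identical compounds
  one <- training[[1]]
  clones <- lapply(1:6, function(i) {
    tc <- one; tc$compound_id <- paste0("clone", i); tc
  })
  ref0 <- build_ad_reference(clones, ad_fixture$params)
  expect_equal(ref0$ts_cutoff, 1.0)
  expect_equal(unname(diff(ref0$dg_range)), 0)
})

test_that("flags are invariant under training-set permutation", {
  training <- ad_fixture$training
  ref_perm <- build_ad_reference(rev(training), ad_fixture$params)
  for (i in c(2, 9, 23)) {
    a <- assess_ad(ad_fixture$ref, ad_fixture$params, training[[i]])
    b <- assess_ad(ref_perm, ad_fixture$params, training[[i]])
    expect_identical(unname(a$flags), unname(b$flags))
  }
})

test_that("self-assessment flag rates match the percentile construction", {
  training <- ad_fixture$training
  reports <- lapply(training, function(tc)
    assess_ad(ad_fixture$ref, ad_fixture$params, tc))
  flags <- t(vapply(reports, function(r) r$flags, integer(5)))
  # criterion 3 flags ~5% of the training compounds it was fitted on
  expect_lte(mean(flags[, "energy"]), 0.10)
  # criteria 4-5 are unions of two 95% conditions: at most ~10% each
  expect_lte(mean(flags[, "decomposition_vdw"]), 0.15)
  expect_lte(mean(flags[, "decomposition_ele"]), 0.15)
  # no training compound violates its own similarity criterion
  expect_equal(sum(flags[, "similarity"]), 0L)
})

test_that("each criterion can be triggered in isolation", {
  ref <- ad_fixture$ref; params <- ad_fixture$params
  training <- ad_fixture$training
  base <- training[[most_central_index(training, params, ref)]]
  expect_equal(assess_ad(ref, params, make_query(base))$ci_total, 0L)

  ab <- c(params$alpha, params$beta)
  S <- ref$energy_covariance
  # direction of steepest free-energy change, scaled to a Mahalanobis
  # distance just inside the threshold: out of range but inside the ellipse
  v1 <- drop(S %*% ab)
  v1 <- v1 / sqrt(drop(t(v1) %*% solve(S) %*% v1))
  pair1 <- ref$energy_centroid + 0.999 * ref$mahalanobis_threshold * v1
  r1 <- assess_ad(ref, params, make_query(base, pair = pair1))
  expect_identical(unname(r1$flags), c(1L, 0L, 0L, 0L, 0L))

  # novel fingerprint only
  used <- Reduce(`|`, lapply(ref$fingerprints, as.logical))
  r2 <- assess_ad(ref, params, make_query(base, fingerprint = as.integer(!used)))
  expect_identical(unname(r2$flags), c(0L, 1L, 0L, 0L, 0L))

  # energy outlier along a level set of the free energy: range stays OK
  v3 <- c(-ab[2], ab[1])
  v3 <- v3 / sqrt(drop(t(v3) %*% solve(S) %*% v3))
  pair3 <- ref$energy_centroid + 3 * ref$mahalanobis_threshold * v3
  r3 <- assess_ad(ref, params, make_query(base, pair = pair3))
  expect_identical(unname(r3$flags), c(0L, 0L, 1L, 0L, 0L))

  # decomposition outliers, one energy type at a time
  qv <- ref$pca_vdw$center + 50 * ref$pca_vdw$od_threshold *
    orthogonal_direction(ref$pca_vdw)
  r4 <- assess_ad(ref, params, make_query(base, decomposition_vdw = qv))
  expect_identical(unname(r4$flags), c(0L, 0L, 0L, 1L, 0L))
  qe <- ref$pca_ele$center + 50 * ref$pca_ele$od_threshold *
    orthogonal_direction(ref$pca_ele)
  r5 <- assess_ad(ref, params, make_query(base, decomposition_ele = qe))
  expect_identical(unname(r5$flags), c(0L, 0L, 0L, 0L, 1L))
})
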