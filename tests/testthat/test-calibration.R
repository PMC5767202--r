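test_that("Cheng-Prusoff conversion follows RT ln IC50", {
  expect_equal(cheng_prusoff_dg(1), 0)
  expect_equal(cheng_prusoff_dg(1e-9, 300), RT300 * log(1e-9))
  expect_equal(cheng_prusoff_dg(1e-9, 300), -51.69, tolerance = 1e-3)
  # monotone: weaker inhibition, less favourable free energy
  expect_gt(cheng_prusoff_dg(1e-6), cheng_prusoff_dg(1e-9))
  expect_error(cheng_prusoff_dg(0), "positive")
  expect_error(cheng_prusoff_dg(-1e-9), "positive")
})

test_that("design rows are Boltzmann-weighted regressors", {
  p <- lie_parameters(0.3, 0.2, -10)
  # single simulation: the raw delta-V pair
  expect_equal(design_row(p, make_energetics(cbind(-50, -20))),
               c(x_vdw = -50, x_ele = -20))
  # equal per-simulation predictions: unweighted means
  # (pairs chosen on a level set of alpha*dv1 + beta*dv2)
  dv_eq <- cbind(c(-50, -48), c(-20, -23))
  expect_equal(per_simulation_dg(p, dv_eq[1, 1], dv_eq[1, 2]),
               per_simulation_dg(p, dv_eq[2, 1], dv_eq[2, 2]))
  expect_equal(design_row(p, make_energetics(dv_eq)),
               c(x_vdw = -49, x_ele = -21.5))
  # three simulations: matches brute-force weighted sums
  dv <- cbind(c(-55, -40, -62), c(-18, -30, -5))
  dg_i <- p$alpha * dv[, 1] + p$beta * dv[, 2] + p$gamma
  e <- exp(-dg_i / RT300)
  w <- e / sum(e)
  expect_equal(design_row(p, make_energetics(dv)),
               c(x_vdw = sum(w * dv[, 1]), x_ele = sum(w * dv[, 2])),
               tolerance = 1e-10)
})

test_that("OLS fitting interpolates, recovers and shifts as linear algebra demands", {
  # 3 compounds in general position, offset free: exact interpolation
  x1 <- c(-50, -40, -60); x2 <- c(-20, -10, -25)
  y <- 0.4 * x1 + 0.1 * x2 - 8
  p <- fit_ols(x1, x2, y, include_offset = TRUE)
  expect_equal(c(p$alpha, p$beta, p$gamma), c(0.4, 0.1, -8),
               tolerance = 1e-8)
  # noiseless synthetic recovery at larger n
  set.seed(3)
  x1 <- rnorm(25, -45, 8); x2 <- rnorm(25, -15, 6)
  y <- 0.33 * x1 + 0.12 * x2 - 13
  p <- fit_ols(x1, x2, y)
  expect_equal(c(p$alpha, p$beta, p$gamma), c(0.33, 0.12, -13),
               tolerance = 1e-8)
  # affine equivariance: shifting all observations moves only gamma
  p_shift <- fit_ols(x1, x2, y + 4.2)
  expect_equal(p_shift$alpha, p$alpha, tolerance = 1e-8)
  expect_equal(p_shift$beta, p$beta, tolerance = 1e-8)
  expect_equal(p_shift$gamma, p$gamma + 4.2, tolerance = 1e-8)
  # gamma fixed to zero when the offset is excluded
  p0 <- fit_ols(x1, x2, y, include_offset = FALSE)
  expect_identical(p0$gamma, 0)
  # collinear design is refused with the offending column named
  expect_error(fit_ols(x1, 2 * x1, y), "collinear.*x_ele")
  expect_error(fit_ols(x1[1:2], x2[1:2], y[1:2]), "at least 3")
})

test_that("single-pose training reduces to one-shot OLS and converges immediately", {
  set.seed(5)
  x1 <- rnorm(12, -45, 8); x2 <- rnorm(12, -15, 6)
  y <- 0.33 * x1 + 0.12 * x2 - 13 + rnorm(12, 0, 1.5)
  training <- lapply(seq_along(y), function(i)
    make_linear_compound(paste0("c", i), x1[i], x2[i], 0, 0, 0, noise = y[i]))
  fit_iter <- calibrate_lie(training)
  fit_once <- fit_ols(x1, x2, y)
  expect_equal(fit_iter$parameters$alpha, fit_once$alpha, tolerance = 1e-10)
  expect_equal(fit_iter$parameters$beta, fit_once$beta, tolerance = 1e-10)
  expect_equal(fit_iter$parameters$gamma, fit_once$gamma, tolerance = 1e-10)
  expect_true(fit_iter$converged)
  expect_lte(fit_iter$n_iterations, 2L)
})

test_that("iterative calibration recovers the generating parameters without noise", {
  spec <- synthetic_spec(n_compounds = 25, noise_sd = 0, seed = 21)
  training <- generate_training_set(spec)
  fit <- calibrate_lie(training, tol = 1e-10, max_iter = 200)
  truth <- attr(training, "truth")$params
  expect_true(fit$converged)
  expect_equal(fit$parameters$alpha, truth$alpha, tolerance = 1e-6)
  expect_equal(fit$parameters$beta, truth$beta, tolerance = 1e-6)
  expect_equal(fit$parameters$gamma, truth$gamma, tolerance = 1e-6)
  expect_lt(fit$metrics$rmse, 1e-6)
})

test_that("noisy calibration is unbiased within Monte-Carlo error", {
  est <- t(vapply(1:20, function(s) {
    training <- generate_training_set(synthetic_spec(seed = 100 + s))
    fit <- calibrate_lie(training, tol = 1e-8)
    c(fit$parameters$alpha, fit$parameters$beta, fit$parameters$gamma,
      fit$se)
  }, numeric(6)))
  truth <- c(0.33, 0.12, -13)
  # Monte-Carlo recovery: the mean estimate sits within 3 standard errors
  # of the mean, and at least 95% of the individual estimates fall within
  # 3 of their reported standard errors (the ~0.3%-per-comparison tail
  # makes an occasional exceedance the expected behaviour, not a defect)
  se_mean <- apply(est[, 1:3], 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est[, 1:3]) - truth) <= 3 * se_mean))
  within3 <- abs(sweep(est[, 1:3], 2, truth)) <= 3 * est[, 4:6]
  expect_gte(mean(within3), 0.95)
})

test_that("leave-one-out refits match explicit hand refits and never leak", {
  # 4-compound single-pose toy set: each LOO refit is a plain 3-point OLS
  x1 <- c(-50, -42, -61, -47); x2 <- c(-20, -9, -26, -31)
  y <- 0.3 * x1 + 0.15 * x2 - 11 + c(0.5, -0.8, 0.2, 0.4)
  training <- lapply(1:4, function(i)
    make_linear_compound(paste0("c", i), x1[i], x2[i], 0, 0, 0, noise = y[i]))
  res <- loo_sdep(training)
  hand <- vapply(1:4, function(i) {
    p <- fit_ols(x1[-i], x2[-i], y[-i])
    p$alpha * x1[i] + p$beta * x2[i] + p$gamma
  }, numeric(1))
  expect_equal(res$loo_predictions$dg_pred_loo, hand, tolerance = 1e-8)
  expect_equal(res$sdep_loo, sqrt(mean((y - hand)^2)), tolerance = 1e-8)
  expect_gte(res$sdep_loo, 0)
  # perfectly linear noiseless data: zero held-out error
  y0 <- 0.3 * x1 + 0.15 * x2 - 11
  lin <- lapply(1:4, function(i)
    make_linear_compound(paste0("c", i), x1[i], x2[i], 0.3, 0.15, -11))
  expect_lt(loo_sdep(lin)$sdep_loo, 1e-8)
  # leakage check: duplicating a compound changes its held-out error
  spec <- synthetic_spec(n_compounds = 6, seed = 31)
  tr6 <- generate_training_set(spec)
  base_loo <- loo_sdep(tr6)$loo_predictions
  dup <- c(tr6, tr6[3])
  dup_loo <- loo_sdep(dup)$loo_predictions
  err_base <- abs(base_loo$dg_obs[3] - base_loo$dg_pred_loo[3])
  err_dup <- abs(dup_loo$dg_obs[3] - dup_loo$dg_pred_loo[3])
  expect_gt(abs(err_base - err_dup), 1e-8)
})

test_that("quality metrics match hand calculations and flag degeneracy", {
  obs <- c(-30, -40); pred <- c(-32, -38)
  m <- quality_metrics(obs, pred)
  expect_equal(m$rmse, 2)
  expect_equal(m$sdep, 2)
  perfect <- quality_metrics(c(-30, -35, -28), c(-30, -35, -28))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r_pearson, 1)
  expect_equal(perfect$rho_spearman, 1)
  anti <- quality_metrics(c(-1, 0, 2), c(1, 0, -2))
  expect_equal(anti$r_pearson, -1)
  flat <- quality_metrics(c(-30, -30, -30), c(-28, -31, -29))
  expect_true(is.na(flat$r_pearson))
  expect_true(is.na(flat$rho_spearman))
})
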