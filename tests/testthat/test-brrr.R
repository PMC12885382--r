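test_that("LDA initialization finds the separating direction", {
  set.seed(1)
  # two subjects separated (and varying) only along feature 1
  Ym <- matrix(0, 8, 6)
  Ym[, 1] <- rnorm(8, 0, 0.01)
  Ym[1:4, 1] <- Ym[1:4, 1] + 5
  Y <- feature_matrix(Ym, subject_id = rep(c("a", "b"), each = 4),
                      segment_label = rep(c("N2a", "N2b", "N2c", "N2d"), 2))
  X <- subject_design_from_meta(Y$row_meta$subject_id, c("a", "b"))
  G <- init_lda(Y, X, K = 1)
  expect_equal(dim(G), c(1, 6))
  expect_true(abs(G[1, 1]) > max(abs(G[1, -1])))
})

test_that("LDA survives zero within-class scatter via the ridge", {
  Ym <- matrix(rep(rnorm(6), each = 4), 4, 6)   # identical rows
  Ym[3:4, ] <- Ym[3:4, ] + 1
  Y <- feature_matrix(Ym, subject_id = rep(c("a", "b"), each = 2),
                      segment_label = rep(c("N2a", "N2b"), 2))
  X <- subject_design_from_meta(Y$row_meta$subject_id, c("a", "b"))
  expect_warning(G <- init_lda(Y, X, K = 2), "ridge")
  expect_true(all(is.finite(G)))
})

test_that("LDA recovers the true projection subspace", {
  sim <- simulate_from_brrr(25, 3, 40, 4, noise_scales = c(0.05, 0.1),
                            seed = 17)
  # with a strong ridge the discriminant subspace aligns with the true
  # projection rows (weak ridges tilt the directions by within-scatter
  # sampling noise without hurting their discriminative value)
  G <- init_lda(sim$Y, sim$X, K = 4, ridge = 50)
  expect_lt(subspace_angle(G, sim$truth$Gamma), 15)

  # the default initialization is still strongly discriminative: the
  # between/within F ratio of every projected direction is enormous
  G0 <- init_lda(sim$Y, sim$X, K = 4)
  proj <- sim$Y$values %*% t(G0)
  subj <- factor(sim$Y$row_meta$subject_id)
  for (k in 1:4) {
    f <- summary(aov(proj[, k] ~ subj))[[1]]$`F value`[1]
    expect_gt(f, 100)
  }
})

test_that("noiseless fits reproduce the least-squares solution", {
  sim <- simulate_from_brrr(15, 2, 25, 3, noise_scales = c(0, 0), seed = 2)
  fit <- gibbs_fit(sim$Y, sim$X, brrr_config(K = 3, n_iter = 400,
                                             burn_in = 200, seed = 5))
  Xm <- sim$X$values
  # least-squares oracle: class means are the exact noiseless fit
  ls_fit <- Xm %*% (diag(1 / colSums(Xm)) %*% crossprod(Xm, sim$Y$values))
  brrr_fit <- Xm %*% fit$posterior_mean$Theta
  rel_err <- norm(brrr_fit - ls_fit, "F") / norm(ls_fit, "F")
  expect_lt(rel_err, 0.05)
  # ptve trace settles near 1 in the noiseless regime
  expect_gt(mean(fit$ptve_trace), 0.97)
  expect_lt(sd(fit$ptve_trace), 0.05)
})

test_that("the sampler is deterministic under a fixed seed", {
  sim <- simulate_from_brrr(10, 2, 15, 2, seed = 3)
  cfg <- brrr_config(K = 2, n_iter = 60, burn_in = 30, seed = 7)
  f1 <- gibbs_fit(sim$Y, sim$X, cfg)
  f2 <- gibbs_fit(sim$Y, sim$X, cfg)
  expect_identical(f1$draws, f2$draws)
})

test_that("moderate-noise simulation recovers the coefficient matrix", {
  sim <- simulate_from_brrr(30, 2, 40, 4, noise_scales = c(0.1, 0.5),
                            seed = 23)
  fit <- gibbs_fit(sim$Y, sim$X, brrr_config(K = 4, n_iter = 500,
                                             burn_in = 250, seed = 1))
  expect_gt(cor(as.vector(fit$posterior_mean$Theta),
                as.vector(sim$truth$Theta)), 0.9)
})

test_that("ptve matches its closed forms", {
  sim <- simulate_from_brrr(12, 2, 20, 3, noise_scales = c(0, 0), seed = 4)
  # exact low-rank response: PTVE = 1
  expect_equal(ptve(list(Psi = sim$truth$Psi, Gamma = sim$truth$Gamma),
                    sim$Y, sim$X), 1, tolerance = 1e-10)
  # no subject effect: PTVE = 0
  expect_equal(ptve(list(Psi = sim$truth$Psi * 0,
                         Gamma = sim$truth$Gamma), sim$Y, sim$X), 0)
  # constant response errors
  Yc <- sim$Y
  Yc$values[] <- 1
  expect_error(ptve(list(Psi = sim$truth$Psi, Gamma = sim$truth$Gamma),
                    Yc, sim$X), "constant")
})

test_that("ptve on noisy data stays near the analytic variance share", {
  sim <- simulate_from_brrr(60, 2, 40, 3, noise_scales = c(0.3, 0.6),
                            seed = 9)
  fitted_true <- (sim$X$values %*% sim$truth$Psi) %*% sim$truth$Gamma
  num <- sum(apply(fitted_true, 2, var))
  # expected additional variance: latent noise through Gamma + residuals
  lat <- 0.3^2 * sum(sim$truth$Gamma^2)
  res <- 0.6^2 * ncol(sim$Y$values)
  share <- num / (num + lat + res)
  expect_equal(ptve(sim$truth, sim$Y, sim$X), share, tolerance = 0.05)
})

test_that("latent projection inverts the generative map", {
  set.seed(13)
  # orthonormal rows: projection recovers coordinates exactly
  G <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))[, 1:4]
  G <- t(G)
  Z <- matrix(rnorm(10 * 4), 10, 4)
  proj <- project_latent(Z %*% G, G)
  expect_equal(proj$coords, Z, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(project_latent(matrix(0, 3, 30), G)$coords,
               matrix(0, 3, 4), ignore_attr = TRUE)

  # generic full-rank gamma with orthogonal-complement noise
  G2 <- matrix(rnorm(3 * 20), 3, 20)
  Z2 <- matrix(rnorm(8 * 3), 8, 3)
  # noise orthogonal to the rows of G2 leaves coordinates untouched
  base <- svd(t(G2))$u
  comp <- diag(20) - base %*% t(base)
  noise <- matrix(rnorm(8 * 20), 8, 20) %*% comp
  proj2 <- project_latent(Z2 %*% G2 + noise, G2)
  expect_equal(proj2$coords, Z2, tolerance = 1e-8, ignore_attr = TRUE)

  # rank-deficient gamma warns and returns the minimum-norm solution
  G3 <- rbind(G2, G2[1, ])
  expect_warning(project_latent(Z2 %*% G2, G3), "rank-deficient")
  expect_error(project_latent(matrix(0, 2, 10), G2), "mismatch")
})

test_that("diagnostics behave on reference chains", {
  set.seed(19)
  x <- rnorm(500)
  expect_true(split_rhat(x) > 0.99 && split_rhat(x) < 1.05)
  expect_gt(ess_bulk(x), 300)
  expect_gt(ess_tail(x), 150)
  # strongly autocorrelated chain has much lower ESS
  y <- as.numeric(arima.sim(list(ar = 0.95), 500))
  expect_lt(ess_bulk(y), ess_bulk(x) / 3)
  # constant chain is undefined and flagged downstream
  expect_true(is.na(split_rhat(rep(1, 500))))
  expect_true(is.na(ess_bulk(rep(1, 500))))
})

test_that("convergence_diagnostics summarizes sampled entries", {
  sim <- simulate_from_brrr(10, 2, 15, 2, seed = 3)
  fit <- gibbs_fit(sim$Y, sim$X, brrr_config(K = 2, n_iter = 300,
                                             burn_in = 100, seed = 7))
  d <- convergence_diagnostics(fit, n_entries = 50, seed = 2)
  expect_equal(nrow(d), 50)
  expect_true(all(c("rhat", "ess_bulk", "ess_tail", "flagged") %in%
                    names(d)))
  expect_true(all(is.finite(d$rhat)))
  s <- attr(d, "summary")
  expect_true(is.finite(s[["ess_bulk_mean"]]))
  # too-short chains rejected
  short <- fit
  short$draws$Psi <- fit$draws$Psi[1:3, , , drop = FALSE]
  expect_error(convergence_diagnostics(short), "4 retained")
})

test_that("elbow selection handles trivial grids", {
  sim <- simulate_from_brrr(10, 2, 15, 2, seed = 3)
  cfg <- brrr_config(K = 2, n_iter = 80, burn_in = 40, seed = 5)
  res <- select_k_elbow(sim$Y, sim$X, k_grid = 2, config = cfg)
  expect_equal(res$chosen_k, 2)
  expect_equal(nrow(res$curve), 1)
  expect_error(select_k_elbow(sim$Y, sim$X, integer(0)), "empty")
  expect_error(select_k_elbow(sim$Y, sim$X, c(5, 2)), "ascending")
})
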