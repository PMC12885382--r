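test_that("identical segments yield no clusters", {
  set.seed(1)
  base <- matrix(abs(rnorm(10 * 50)) + 1, 10)
  A <- array(NA_real_, c(10, 3, 50))
  for (j in 1:3) A[, j, ] <- base
  cl <- cluster_permutation_test(A, n_perm = 100, seed = 2)
  expect_equal(nrow(cl$clusters), 0)
  expect_equal(cl$dfs, c(d1 = 2, d2 = 10))
})

test_that("an injected spindle-range shift is recovered as the
           minimum-p cluster", {
  set.seed(3)
  nf <- 171
  freqs <- seq(1, 42.6, length.out = nf)
  A <- array(rnorm(30 * 2 * nf, sd = 0.5), c(30, 2, nf))
  sb <- which(freqs >= 12 & freqs <= 15)
  A[, 2, sb] <- A[, 2, sb] + 1
  cl <- cluster_permutation_test(A, n_perm = 500, seed = 4, freqs = freqs)
  expect_gt(nrow(cl$clusters), 0)
  top <- cl$clusters[which.min(cl$clusters$p), ]
  expect_lt(top$p, 0.01)
  expect_true(top$freq_low <= 15 && top$freq_high >= 12)  # overlap
})

test_that("cluster test is reproducible and validates input", {
  set.seed(5)
  A <- array(rnorm(8 * 2 * 40), c(8, 2, 40))
  c1 <- cluster_permutation_test(A, n_perm = 50, seed = 9)
  c2 <- cluster_permutation_test(A, n_perm = 50, seed = 9)
  expect_identical(c1$clusters, c2$clusters)
  Abad <- A
  Abad[1, 1, 1] <- NA
  expect_error(cluster_permutation_test(Abad, n_perm = 10), "unequal")
  expect_error(cluster_permutation_test(A[, 1, , drop = FALSE]),
               "2 segments")
  # conventional df option widens the error df
  c3 <- cluster_permutation_test(A, n_perm = 10, seed = 1,
                                 df_convention = "conventional")
  expect_equal(unname(c3$dfs["d2"]), 7)
})

test_that("mantel test handles exact association and affine invariance", {
  set.seed(6)
  D <- matrix(abs(rnorm(400)), 20)
  m <- mantel_test(D, D, n_perm = 999, seed = 7)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 1000)
  m2 <- mantel_test(D, 2 * D + 3, n_perm = 99, seed = 8)
  expect_equal(m2$r, 1)
  expect_error(mantel_test(D, matrix(1, 20, 20), n_perm = 9), "constant")
  expect_error(mantel_test(D[1:3, 1:3], D[1:3, 1:3]), "4 subjects")
})

test_that("mantel agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(9)
  n <- 15
  base <- matrix(rnorm(n * 5), n)
  D1 <- as.matrix(dist(base, method = "manhattan"))
  D2 <- as.matrix(dist(base + rnorm(n * 5, sd = 0.5),
                       method = "manhattan"))
  ours <- mantel_test(D1, D2, n_perm = 999, seed = 10)
  ref <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.02)
})

test_that("emg noise covariate equals the log-ratio identities", {
  cohort <- data.frame(subject_id = c("a", "b", "c"),
                       emg_N2a = c(1, 2, exp(1) * 3),
                       emg_N2b = c(1, 2, 3))
  nv <- emg_noise_covariate(cohort, "N2a", "N2b")
  expect_equal(nv$noise, c(0, 0, 1))
  set.seed(11)
  r1 <- runif(50, 0.1, 5)
  r2 <- runif(50, 0.1, 5)
  co <- data.frame(subject_id = as.character(1:50), emg_N1a = r1,
                   emg_N1b = r2)
  nv2 <- emg_noise_covariate(co, "N1a", "N1b")
  expect_equal(nv2$noise, abs(log(r1) - log(r2)), tolerance = 1e-12)
  bad <- data.frame(subject_id = "z", emg_N2a = -1, emg_N2b = 2)
  expect_error(emg_noise_covariate(bad, "N2a", "N2b"), "z")
  expect_error(emg_noise_covariate(cohort, "N2c", "N2d"), "emg_N2c")
})

test_that("differentiability regression reproduces known effects and
           rejects aliased designs", {
  set.seed(12)
  n <- 400
  cohort <- data.frame(subject_id = sprintf("s%03d", 1:n),
                       age = runif(n, 0.5, 18),
                       sex = sample(c("F", "M"), n, TRUE),
                       cap = sample(c("small", "FT"), n, TRUE))
  noise <- data.frame(subject_id = cohort$subject_id,
                      noise = abs(rnorm(n, 0, 0.2)))
  scores <- 2 + 0.1 * cohort$age + rnorm(n, 0, 0.3)
  names(scores) <- cohort$subject_id
  res <- differentiability_regression(scores, cohort, noise)
  co <- res$coefficients
  age_row <- co[co$term == "age", ]
  expect_lt(abs(age_row$estimate - 0.1), 0.02)
  expect_true(age_row$ci_low < 0.1 && age_row$ci_high > 0.1)
  expect_setequal(co$term, c("(Intercept)", "noise", "sexM", "age",
                             "capFT", "noise:sexM"))
  expect_equal(res$fit_stats$f_df[1], 5)

  # constant scores: every slope is zero, intercept is the constant
  sc <- rep(2.5, n)
  names(sc) <- cohort$subject_id
  res0 <- differentiability_regression(sc, cohort, noise)
  co0 <- res0$coefficients
  expect_equal(co0$estimate[co0$term == "(Intercept)"], 2.5)
  expect_equal(co0$estimate[co0$term != "(Intercept)"], rep(0, 5),
               tolerance = 1e-10)

  # single-sex cohort with the interaction -> aliased -> error
  single <- cohort
  single$sex <- "F"
  expect_error(differentiability_regression(scores, single, noise),
               "alias|contrasts|rank")

  # N1 variant adds the age-by-sex interaction
  resN1 <- differentiability_regression(scores, cohort, noise,
                                        include_age_sex_interaction = TRUE)
  expect_true("sexM:age" %in% resN1$coefficients$term)
})

test_that("regression output matches a normal-equations solve", {
  set.seed(13)
  n <- 60
  cohort <- data.frame(subject_id = as.character(1:n),
                       age = runif(n, 1, 15),
                       sex = rep(c("F", "M"), n / 2),
                       cap = rep(c("small", "FT"), each = n / 2))
  noise <- data.frame(subject_id = cohort$subject_id,
                      noise = abs(rnorm(n)))
  scores <- rnorm(n)
  names(scores) <- cohort$subject_id
  res <- differentiability_regression(scores, cohort, noise)
  df <- merge(merge(data.frame(subject_id = names(scores),
                               score = unname(scores)), cohort, "subject_id"),
              noise, "subject_id")
  M <- model.matrix(~ noise + factor(sex, c("F", "M")) + age +
                      factor(cap, c("small", "FT")) +
                      noise:factor(sex, c("F", "M")), df)
  beta <- solve(crossprod(M), crossprod(M, df$score))
  expect_equal(sort(res$coefficients$estimate), sort(as.vector(beta)),
               tolerance = 1e-8)
})

test_that("cubic age regression recovers polynomials exactly and flags
           curvature", {
  age <- seq(0.2, 18, length.out = 40)
  auc <- 2 + 1.5 * age - 0.3 * age^2 + 0.01 * age^3
  res <- auc_age_regression(auc, age)
  expect_equal(res$coefficients$estimate, c(2, 1.5, -0.3, 0.01),
               tolerance = 1e-8)

  # inverted-U cohort: negative quadratic term with CI excluding zero
  set.seed(14)
  age2 <- runif(300, 0.2, 18)
  auc2 <- 10 + 6 * age2 - 0.5 * age2^2 + rnorm(300, 0, 2)
  res2 <- auc_age_regression(auc2, age2)
  q <- res2$coefficients[res2$coefficients$term == "age^2", ]
  expect_lt(q$estimate, 0)
  expect_lt(q$ci_high, 0)

  # constant response: all slopes zero
  res3 <- auc_age_regression(rep(5, 40), age)
  expect_equal(res3$coefficients$estimate[-1], rep(0, 3),
               tolerance = 1e-10)
  expect_error(auc_age_regression(auc[1:4], age[1:4]), "n > degree")
  expect_error(auc_age_regression(rep(1, 10), rep(3, 10)), "degenerate")
})

test_that("artifact-age regression fits exactly with two points and
           recovers a small negative slope", {
  res <- artifact_age_regression(c(1, 2), c(3, 5))
  expect_equal(res$coefficients$estimate, c(-0.5, 0.5), tolerance = 1e-10)
  expect_equal(res$fit_stats$r_squared, 1)

  set.seed(15)
  age <- runif(700, 0.2, 18)
  noise <- pmax(0.3 - 0.005 * age + rnorm(700, 0, 0.02), 0)
  res2 <- artifact_age_regression(noise, age)
  sl <- res2$coefficients[2, ]
  expect_lt(sl$estimate, 0)
  expect_lt(sl$ci_high, 0)
  expect_error(artifact_age_regression(c(1, 2, 3), c(1, 2)), "lengths")
})
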