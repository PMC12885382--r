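test_that("band definition reproduces the 13 standard bands", {
  b <- define_bands()
  expect_equal(nrow(b), 13)
  expect_equal(c(b$low[1], b$high[1]), c(1, 3))
  expect_equal(c(b$low[13], b$high[13]), c(38.2, 42.6))
  expect_equal(diff(b$width), rep(0.2, 12))
  expect_equal(sum(b$width), 41.6)
  expect_equal(b$low[-1], b$high[-13])   # contiguous tiling
  expect_equal(attr(b, "edges"),
               c(1, 3, 5.2, 7.6, 10.2, 13, 16, 19.2, 22.6, 26.2, 30, 34,
                 38.2, 42.6))
})

test_that("band-pass is linear, zero-phase and attenuates drift", {
  n <- 250 * 900
  tt <- (0:(n - 1)) / 250
  expect_equal(sleepfp:::fft_bandpass(rep(0, n), 250), rep(0, n))
  drift <- sin(2 * pi * 0.1 * tt)
  att <- 20 * log10(sd(sleepfp:::fft_bandpass(drift, 250)) / sd(drift))
  expect_lt(att, -20)
  pass <- sin(2 * pi * 10 * tt)
  ratio <- sd(sleepfp:::fft_bandpass(pass, 250)) / sd(pass)
  expect_equal(ratio, 1, tolerance = 1e-6)
})

test_that("epoching yields the six labeled analysis segments", {
  sp <- make_subject_spec(offset = 0.3)
  rec <- simulate_recording(sp, seed = 3)
  eps <- bandpass_and_epoch(rec)
  expect_length(eps, 6)
  labs <- vapply(eps, `[[`, "", "segment_label")
  expect_equal(labs, segment_labels())
  expect_equal(vapply(eps, `[[`, "", "stage"),
               c("N1", "N1", "N2", "N2", "N2", "N2"))
  onsets <- vapply(eps, `[[`, 0, "onset")
  expect_true(all(diff(onsets) > 0))      # chronological
  # too-short recording errors with the subject named
  short <- rec
  short$data <- rec$data[, 1:(250 * 500)]
  expect_error(bandpass_and_epoch(short), "T001")
})

test_that("welch psd satisfies Parseval for a pure sinusoid", {
  tt <- (0:(15000 - 1)) / 250
  ps <- welch_psd(matrix(sin(2 * pi * 10 * tt), 1))
  expect_equal(diff(ps$freqs[1:2]), 250 / 1024)
  power <- loop_trapz(ps$freqs, ps$psd[1, ], 0, 125)
  expect_equal(power, 0.5, tolerance = 0.05 * 0.5)
  expect_equal(ps$freqs[which.max(ps$psd[1, ])], 10, tolerance = 0.25)
})

test_that("welch psd is stable across halves of a stationary signal", {
  set.seed(21)
  x <- rnorm(2 * 15000)
  p1 <- welch_psd(matrix(x[1:15000], 1))
  p2 <- welch_psd(matrix(x[15001:30000], 1))
  keep <- p1$freqs >= 1 & p1$freqs <= 42.6
  rel <- abs(p1$psd[1, keep] - p2$psd[1, keep]) /
    ((p1$psd[1, keep] + p2$psd[1, keep]) / 2)
  expect_lt(median(rel), 0.2)
})

test_that("welch psd of silence is zero and wrong rate errors", {
  ps <- welch_psd(matrix(0, 2, 15000))
  expect_true(all(ps$psd == 0))
  expect_error(welch_psd(matrix(0, 1, 15000), fs = 500), "250")
})

test_that("relative bandpower matches closed forms and the quadrature
           oracle", {
  freqs <- (0:512) * 250 / 1024
  flat <- make_psd_segment(matrix(1, 19, 513))
  rb <- relative_bandpower(flat)
  expect_length(rb, 247)
  expect_equal(unname(rb[1]), 2 / 41.6, tolerance = 1e-12)
  for (ch in 1:19) {
    expect_equal(sum(rb[(ch - 1) * 13 + 1:13]), 1, tolerance = 1e-9)
  }

  # power confined strictly inside band 6 (13-16 Hz)
  conc <- matrix(0, 19, 513)
  conc[, freqs > 13.5 & freqs < 15.5] <- 5
  rbc <- relative_bandpower(make_psd_segment(conc))
  expect_equal(unname(rbc[6]), 1)
  expect_equal(unname(sum(rbc[1:13])), 1)
  expect_equal(unname(rbc[1]), 0)

  # alpha-peak spectrum against the independent quadrature oracle
  psd <- matrix(rep(10 / pmax(freqs, 0.5)^1.3 +
                      3 * exp(-(freqs - 10)^2 / 2), 2),
                2, byrow = TRUE)
  rba <- relative_bandpower(make_psd_segment(psd[1:2, , drop = FALSE]))
  b <- define_bands()
  bp <- vapply(seq_len(13), function(k) {
    loop_trapz(freqs, psd[1, ], b$low[k], b$high[k])
  }, 0)
  expect_equal(unname(rba[1:13]), bp / sum(bp), tolerance = 1e-6)

  # degenerate channel errors
  dead <- matrix(1, 3, 513)
  dead[2, ] <- 0
  expect_error(relative_bandpower(make_psd_segment(dead)), "degenerate")
})

test_that("psd auc equals the quadrature oracle", {
  freqs <- (0:512) * 250 / 1024
  expect_equal(psd_auc(make_psd_segment(matrix(0, 19, 513))), 0)
  expect_equal(psd_auc(make_psd_segment(matrix(2.5, 19, 513))),
               2.5 * 41.6, tolerance = 1e-9)
  set.seed(11)
  psd <- matrix(rep(abs(rnorm(513)) + 0.1, 4), 4, byrow = TRUE)
  seg <- make_psd_segment(psd)
  expect_equal(psd_auc(seg), loop_trapz(freqs, colMeans(psd), 1, 42.6),
               tolerance = 1e-9)
})

test_that("matrix assembly orders rows and validates completeness", {
  set.seed(5)
  segs <- list()
  for (sid in c("S2", "S1", "S3")) {
    for (lab in c("N2b", "N2a")) {
      segs[[length(segs) + 1]] <-
        make_psd_segment(matrix(abs(rnorm(19 * 513)) + 0.1, 19),
                         subject_id = sid, label = lab)
    }
  }
  m <- build_matrices(segs, segment_labels_used = c("N2a", "N2b"))
  expect_equal(dim(m$Y$values), c(6, 247))
  expect_equal(dim(m$X$values), c(6, 3))
  expect_true(all(rowSums(m$X$values) == 1))
  expect_equal(colSums(m$X$values), c(2, 2, 2), ignore_attr = TRUE)
  expect_equal(m$Y$row_meta$subject_id, rep(c("S1", "S2", "S3"), each = 2))
  expect_equal(m$Y$row_meta$segment_label, rep(c("N2a", "N2b"), 3))

  single <- build_matrices(segs[3:4], segment_labels_used = c("N2a", "N2b"))
  expect_equal(single$X$values, matrix(1, 2, 1), ignore_attr = TRUE)

  expect_error(build_matrices(c(segs, segs[1]),
                              segment_labels_used = c("N2a", "N2b")),
               "duplicate")
  expect_error(build_matrices(segs[-1],
                              segment_labels_used = c("N2a", "N2b")),
               "missing")
})

test_that("z-scoring standardizes train and carries parameters", {
  set.seed(6)
  Y <- feature_matrix(matrix(rnorm(40 * 10, 5, 3), 40),
                      subject_id = rep(sprintf("s%d", 1:20), each = 2),
                      segment_label = rep(c("N2a", "N2b"), 20))
  z <- zscore_features(Y)
  expect_true(all(abs(colMeans(z$values)) < 1e-10))
  expect_true(all(abs(apply(z$values, 2, sd) - 1) < 1e-10))
  expect_true(z$standardized)

  z2 <- zscore_features(Y, Y)
  expect_equal(z2$train$values, z2$applied$values)

  # held-out data from the same distribution is near-centered
  set.seed(7)
  big <- matrix(rnorm(1000 * 10, 5, 3), 1000)
  train <- feature_matrix(matrix(rnorm(1000 * 10, 5, 3), 1000),
                          subject_id = as.character(1:1000),
                          segment_label = rep("N2a", 1000))
  held <- feature_matrix(big, subject_id = as.character(1:1000),
                         segment_label = rep("N2b", 1000))
  za <- zscore_features(train, held)
  expect_true(all(abs(colMeans(za$applied$values)) < 5 / sqrt(1000)))

  # zero-variance column warned and floored
  Yz <- Y
  Yz$values[, 3] <- 7
  expect_warning(zscore_features(Yz), "zero-variance")
})

test_that("pipeline features are deterministic and 247-dimensional", {
  fx <- unit_cohort()
  expect_equal(ncol(fx$Y$values), 247)
  # per-channel relative powers sum to 1 on every generated row
  for (r in sample(nrow(fx$Y$values), 5)) {
    sums <- vapply(1:19, function(ch) {
      sum(fx$Y$values[r, (ch - 1) * 13 + 1:13])
    }, 0)
    expect_equal(sums, rep(1, 19), tolerance = 1e-9)
  }
  # same recording in -> identical features out
  rerun <- simulate_cohort_psd(fx$gen$subjects[1], seed = 31)
  f1 <- relative_bandpower(rerun$segments[[3]])
  expect_identical(unname(f1), unname(fx$Y$values[3, ]))
})
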