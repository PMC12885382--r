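# shared fixtures, memoized per test run (expensive signal simulations
# are built once and reused by the unit tests; acceptance tests build
# their own inputs)
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, expr, envir = .fx)
  get(name, envir = .fx)
}

# a bare subject_spec with full control over the spectral content
make_subject_spec <- function(subject_id = "T001", age = 6,
                              offset = -Inf, exponent = 1.2,
                              peaks = list(), channel_gain = rep(1, 19),
                              emg_level = 0, sex = "F",
                              config = cohort_config()) {
  structure(list(
    subject_id = subject_id, age = age, sex = sex,
    cap = if (age < 5) "small" else "FT",
    aperiodic_offset = offset, aperiodic_exponent = exponent,
    peak_list = peaks, channel_gain = channel_gain,
    emg_level = emg_level, idiosyncrasy_seed = 1L, config = config
  ), class = "subject_spec")
}

peak <- function(center, bw = 1.5, amplitude = 1, n1 = 1, n2 = 1) {
  list(center = center, bw = bw, amplitude = amplitude,
       stage_gain = c(N1 = n1, N2 = n2))
}

# synthetic psd_segment on the Welch grid
make_psd_segment <- function(psd, subject_id = "P1", label = "N2a") {
  nh <- ncol(psd)
  structure(list(subject_id = subject_id, segment_label = label,
                 stage = segment_stage(label),
                 freqs = (0:(nh - 1)) * 250 / 1024, psd = psd),
            class = "psd_segment")
}

welch_nbins <- 513

# small high-idiosyncrasy signal-level cohort used across unit tests
unit_cohort <- function() {
  fixture("unit_cohort", {
    g <- generate_cohort(12, seed = 31,
                         config = cohort_config_high_idiosyncrasy())
    sim <- simulate_cohort_psd(g$subjects, seed = 31)
    mats <- build_matrices(sim$segments)
    list(gen = g, sim = sim, Y = mats$Y, X = mats$X)
  })
}

# brute-force oracles -------------------------------------------------

loop_l1 <- function(A, B) {
  n <- nrow(A)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sum(abs(A[i, ] - B[j, ]))
  }
  D
}

loop_pearson <- function(A, B) {
  n <- nrow(A)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- A[i, ]; b <- B[j, ]
    C[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
      ((length(a) - 1) * sd(a) * sd(b))
  }
  C
}

loop_differentiability <- function(V, kind) {
  n <- nrow(V)
  out <- numeric(n)
  for (i in seq_len(n)) {
    others <- V[i, setdiff(seq_len(n), i)]
    z <- (V[i, i] - mean(others)) / sd(others)
    out[i] <- if (kind == "l1_distance") -z else z
  }
  out
}

# independent trapezoid quadrature written as an explicit loop
loop_trapz <- function(x, y, lo, hi) {
  xs <- sort(unique(c(lo, hi, x[x > lo & x < hi])))
  yi <- approx(x, y, xs)$y
  total <- 0
  for (i in seq_len(length(xs) - 1)) {
    total <- total + (xs[i + 1] - xs[i]) * (yi[i] + yi[i + 1]) / 2
  }
  total
}

# principal angle (degrees) between the row spaces of two matrices
subspace_angle <- function(A, B) {
  qa <- qr.Q(qr(t(A)))
  qb <- qr.Q(qr(t(B)))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(sv)))) * 180 / pi
}
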