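#' Default cohort-generator configuration
#'
#' Parameter table driving [generate_cohort()] and [simulate_recording()].
#' Defaults emulate a pediatric clinical sleep-EEG cohort: a right-skewed
#' age distribution (most subjects under 5 years), an inverted-U
#' relationship between age and total spectral power, sleep spindles
#' (12-15 Hz) whose amplitude grows with age and is stronger in N2 than
#' in N1 sleep, per-subject stable spectral idiosyncrasies, and
#' per-segment EMG artifact levels whose variability shrinks with age.
#'
#' @param age_shape,age_scale Gamma parameters of the age distribution in
#'   years. The defaults give mean ~4.6 y and SD ~4.3 y.
#' @param age_min,age_max Truncation bounds for age (years).
#' @param aperiodic_exponent_range Range of the 1/f^chi exponent chi.
#' @param offset_base Baseline log10 power offset of the aperiodic
#'   component (log10 uV^2/Hz at 1 Hz).
#' @param offset_age_gain,offset_age_tau Size and timescale (years) of the
#'   inverted-U age effect on total power: the age term is
#'   `gain * (age/tau) * exp(1 - age/tau)`, peaking at `tau` years.
#' @param offset_idio_sd Between-subject SD of the aperiodic offset
#'   (log10 units); the stable per-subject power idiosyncrasy.
#' @param channel_gain_sd SD of per-channel log-normal gains; the stable
#'   per-subject topographic idiosyncrasy.
#' @param spindle_freq_range Range of the spindle peak center (Hz).
#' @param spindle_amp_base,spindle_amp_age_gain,spindle_age_tau Spindle
#'   amplitude at age 0, its asymptotic age gain, and the maturation
#'   timescale (years): amplitude `base + gain*(1-exp(-age/tau))`.
#' @param spindle_n2_gain,spindle_n1_gain Stage gains of the spindle peak;
#'   N2 strictly larger than N1.
#' @param spindle_amp_idio_sd Log-normal SD of per-subject spindle
#'   amplitude.
#' @param alpha_prob Probability that a subject has a low-alpha/theta
#'   range peak (emerges with maturation; applied for ages > 1 y).
#' @param alpha_amp Amplitude of that peak.
#' @param emg_level_meanlog,emg_level_sdlog Log-normal parameters of the
#'   per-subject EMG RMS scale (uV).
#' @param emg_seg_sd_base,emg_seg_sd_age_slope Between-segment log-normal
#'   SD of EMG amplitude at age 0 and its (negative) linear age slope;
#'   floor at 0.05.
#' @param segment_drift_sd SD of the slow multiplicative random-walk gain
#'   across the six analysis segments (per-subject spectral
#'   non-stationarity; makes far-apart segments less alike).
#' @param wake_contamination Probability that an N1 epoch is replaced by
#'   a wake-like epoch (spindle silenced, EMG doubled). Default 0 (exact
#'   stage labels).
#' @return A named list of class `sleepfp_config`.
#' @export
cohort_config <- function(age_shape = 1.15,
                          age_scale = 4.0,
                          age_min = 0.1,
                          age_max = 19,
                          aperiodic_exponent_range = c(0.8, 2.0),
                          offset_base = 0.3,
                          offset_age_gain = 0.8,
                          offset_age_tau = 2.0,
                          offset_idio_sd = 0.15,
                          channel_gain_sd = 0.12,
                          spindle_freq_range = c(12.5, 14.5),
                          spindle_amp_base = 0.4,
                          spindle_amp_age_gain = 1.2,
                          spindle_age_tau = 3.0,
                          spindle_n2_gain = 2.0,
                          spindle_n1_gain = 0.6,
                          spindle_amp_idio_sd = 0.25,
                          alpha_prob = 0.7,
                          alpha_amp = 0.8,
                          emg_level_meanlog = 0.0,
                          emg_level_sdlog = 0.4,
                          emg_seg_sd_base = 0.35,
                          emg_seg_sd_age_slope = -0.012,
                          segment_drift_sd = 0.05,
                          wake_contamination = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$age_min > 0, cfg$age_max > cfg$age_min,
            cfg$spindle_n2_gain > cfg$spindle_n1_gain)
  structure(cfg, class = "sleepfp_config")
}

#' High-idiosyncrasy cohort configuration
#'
#' A [cohort_config()] variant with strong, stable between-subject
#' spectral idiosyncrasies (larger channel-gain, offset and spindle
#' amplitude variation) and little within-recording drift: the regime
#' in which individuals are well differentiable from their sleep
#' spectra. Used as the demo scenario for fingerprinting performance.
#'
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `sleepfp_config`.
#' @export
cohort_config_high_idiosyncrasy <- function(...) {
  defaults <- list(channel_gain_sd = 0.3, offset_idio_sd = 0.3,
                   segment_drift_sd = 0.02, spindle_amp_idio_sd = 0.5)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(cohort_config, defaults)
}

#' The 19-channel 10-20 montage used throughout
#' @return Character vector of 19 channel labels.
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Labels of the six analysis segments
#' @return `c("N1a","N1b","N2a","N2b","N2c","N2d")`.
#' @export
segment_labels <- function() c("N1a", "N1b", "N2a", "N2b", "N2c", "N2d")

#' Sleep stage of each segment label
#' @param labels Segment labels.
#' @return `"N1"` or `"N2"` per label.
#' @export
segment_stage <- function(labels) {
  ifelse(substr(labels, 1, 2) == "N1", "N1", "N2")
}

# Onset (s) of each 60-s analysis segment within the 900-s recording.
# N1a/N1b span the N1 block (0-300 s); N2a..N2d the N2 block (300-900 s),
# with N2a,N2b adjacent and N2c,N2d later in the recording.
segment_onsets <- function() {
  c(N1a = 0, N1b = 240, N2a = 300, N2b = 360, N2c = 600, N2d = 840)
}

draw_age <- function(n, cfg) {
  out <- numeric(0)
  while (length(out) < n) {
    a <- stats::rgamma(n, shape = cfg$age_shape, scale = cfg$age_scale)
    a <- a[a >= cfg$age_min & a <= cfg$age_max]
    out <- c(out, a)
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort of subject specifications
#'
#' Draws `n_subjects` subject parameter sets. Each subject carries an
#' aperiodic (1/f) background whose offset follows an inverted-U in age,
#' a sleep-spindle peak (12-15 Hz) with a strictly larger gain in N2 than
#' N1 and amplitude increasing with age, optional slower oscillatory
#' peaks, stable per-channel gains, and a per-segment EMG artifact scale.
#' Per-subject parameters are deterministic given `(seed, subject index)`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed; the whole cohort is reproducible.
#' @param config A [cohort_config()] list.
#' @return A list with `subjects` (list of `subject_spec`) and `cohort`
#'   (data.frame: subject_id, age, sex, cap, emg_level).
#' @export
generate_cohort <- function(n_subjects, seed = 1, config = cohort_config()) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 ||
      n_subjects < 2 || n_subjects != round(n_subjects)) {
    stop("`n_subjects` must be a single integer >= 2")
  }
  cfg <- config
  n <- as.integer(n_subjects)
  set.seed(as.integer(seed))
  ages <- draw_age(n, cfg)
  sexes <- sample(c("F", "M"), n, replace = TRUE)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    # per-subject substream: deterministic given (seed, i)
    sub_seed <- (as.integer(seed) * 10007L + i * 131L) %% .Machine$integer.max
    set.seed(sub_seed)
    age <- ages[i]
    exponent <- stats::runif(1, cfg$aperiodic_exponent_range[1],
                             cfg$aperiodic_exponent_range[2])
    age_term <- cfg$offset_age_gain * (age / cfg$offset_age_tau) *
      exp(1 - age / cfg$offset_age_tau)
    offset <- cfg$offset_base + age_term +
      stats::rnorm(1, 0, cfg$offset_idio_sd)
    channel_gain <- exp(stats::rnorm(19, 0, cfg$channel_gain_sd))
    sp_center <- stats::runif(1, cfg$spindle_freq_range[1],
                              cfg$spindle_freq_range[2])
    sp_amp <- (cfg$spindle_amp_base + cfg$spindle_amp_age_gain *
                 (1 - exp(-age / cfg$spindle_age_tau))) *
      exp(stats::rnorm(1, 0, cfg$spindle_amp_idio_sd))
    peaks <- list(list(center = sp_center, bw = 1.5, amplitude = sp_amp,
                       stage_gain = c(N1 = cfg$spindle_n1_gain,
                                      N2 = cfg$spindle_n2_gain)))
    if (age > 1 && stats::runif(1) < cfg$alpha_prob) {
      # slower oscillatory peak whose frequency matures from theta to alpha
      ac <- 4 + 6 * (1 - exp(-age / 6)) + stats::rnorm(1, 0, 0.5)
      peaks <- c(peaks, list(list(center = max(2, ac), bw = 2,
                                  amplitude = cfg$alpha_amp *
                                    exp(stats::rnorm(1, 0, 0.3)),
                                  stage_gain = c(N1 = 1, N2 = 1))))
    }
    emg_level <- exp(stats::rnorm(1, cfg$emg_level_meanlog,
                                  cfg$emg_level_sdlog))
    subjects[[i]] <- structure(list(
      subject_id = sprintf("S%04d", i),
      age = age,
      sex = sexes[i],
      cap = if (age < 5) "small" else "FT",
      aperiodic_offset = offset,
      aperiodic_exponent = exponent,
      peak_list = peaks,
      channel_gain = channel_gain,
      emg_level = emg_level,
      idiosyncrasy_seed = sub_seed,
      config = cfg
    ), class = "subject_spec")
  }
  cohort <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    age = vapply(subjects, `[[`, 0, "age"),
    sex = vapply(subjects, `[[`, "", "sex"),
    cap = vapply(subjects, `[[`, "", "cap"),
    emg_level = vapply(subjects, `[[`, 0, "emg_level"),
    stringsAsFactors = FALSE
  )
  list(subjects = subjects, cohort = cohort)
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf("<subject_spec %s: age %.1f y, sex %s, cap %s, %d peak(s)>\n",
              x$subject_id, x$age, x$sex, x$cap, length(x$peak_list)))
  invisible(x)
}
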