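# Spectrally shaped Gaussian noise: returns a length-n signal whose
# one-sided PSD approximates S(f) given by psd_vals on the rfft grid.
# psd_vals: length floor(n/2)+1 vector of target PSD (uV^2/Hz) at
# frequencies (0:(n/2))*fs/n.
shaped_noise <- function(n, fs, psd_vals) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  nh <- length(psd_vals)                  # floor(n/2)+1
  amp <- sqrt(pmax(psd_vals, 0) * fs / 2)
  amp[1] <- 0                             # no DC
  mult <- numeric(n)
  mult[seq_len(nh)] <- amp
  if (n %% 2 == 0) {
    mult[n:(nh + 1)] <- amp[2:(nh - 1)]   # mirror (exclude DC, Nyquist)
  } else {
    mult[n:(nh + 1)] <- amp[2:nh]
  }
  Re(stats::fft(X * mult, inverse = TRUE)) / n
}

# rfft frequency grid for length-n signal at rate fs
rfft_freqs <- function(n, fs) (0:(n %/% 2)) * fs / n

#' Simulate a 900-s 19-channel sleep-EEG recording
#'
#' Generates the subject's signal as the sum of three components per
#' channel: (i) an aperiodic 1/f^chi background with the subject's
#' offset and exponent, realized by exact frequency-domain spectral
#' shaping of white noise; (ii) narrowband Gaussian oscillatory
#' components at each configured peak, with stage-dependent power gain
#' (the spindle peak is stronger in N2 than N1); (iii) broadband
#' high-frequency EMG-like noise scaled to the subject's per-segment RMS
#' level. A slow multiplicative random-walk gain across the fifteen 60-s
#' epochs models within-recording non-stationarity of the neural
#' components. The first 300 s are annotated N1, the last 600 s N2.
#'
#' @param spec A `subject_spec` from [generate_cohort()].
#' @param seed Integer seed; the recording is reproducible given
#'   `(spec, seed)`.
#' @return A `sleep_recording`: list with `subject_id`, `sampling_rate`
#'   (250), `channels` (19 labels), `data` (19 x 225000 matrix, uV),
#'   `stage_annotation` (onset, duration, stage), and
#'   `emg_rms_by_segment` (named over [segment_labels()]).
#' @export
simulate_recording <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "subject_spec"))
  cfg <- spec$config
  fs <- 250
  dur <- 900
  n <- fs * dur
  set.seed(as.integer(seed) %% .Machine$integer.max)
  freqs <- rfft_freqs(n, fs)
  nh <- length(freqs)

  # aperiodic background PSD, flattened below 0.5 Hz (drifts are removed
  # by the band-pass anyway; avoids the 1/f singularity)
  f_eff <- pmax(freqs, 0.5)
  bg_psd <- 10^spec$aperiodic_offset / f_eff^spec$aperiodic_exponent

  # stage power-gain envelope per sample for each peak
  t_stage <- rep(c("N1", "N2"), c(300 * fs, 600 * fs))
  n_epochs <- dur / 60
  epoch_of_sample <- rep(seq_len(n_epochs), each = 60 * fs)

  # slow drift of neural gain across epochs (power gain)
  drift <- exp(cumsum(stats::rnorm(n_epochs, 0, cfg$segment_drift_sd)))
  drift_env <- sqrt(drift[epoch_of_sample])

  # wake contamination: selected N1 epochs lose the spindle and double EMG
  wake_epochs <- integer(0)
  if (cfg$wake_contamination > 0) {
    n1_epochs <- which(seq_len(n_epochs) <= 5)
    wake_epochs <- n1_epochs[stats::runif(length(n1_epochs)) <
                               cfg$wake_contamination]
  }

  emg_env <- exp(stats::rnorm(n_epochs, 0,
                              max(0.05, cfg$emg_seg_sd_base +
                                    cfg$emg_seg_sd_age_slope * spec$age)))
  emg_env[wake_epochs] <- emg_env[wake_epochs] * 2

  # EMG PSD shape: flat 25-125 Hz with raised-cosine onset 15-25 Hz,
  # unit total power (scaled per channel below)
  emg_shape <- ifelse(freqs >= 25, 1,
                      ifelse(freqs <= 15, 0,
                             0.5 * (1 - cos(pi * (freqs - 15) / 10))))
  emg_shape <- emg_shape / sum(emg_shape * fs / n)   # integrates to 1

  data <- matrix(0, nrow = 19, ncol = n)
  emg_component_sq <- numeric(n)  # channel-mean squared EMG, accumulated

  for (ch in 1:19) {
    g <- spec$channel_gain[ch]
    sig <- shaped_noise(n, fs, bg_psd * g) * drift_env
    for (pk in spec$peak_list) {
      sigma <- pk$bw / 2.355
      pk_psd <- pk$amplitude^2 * exp(-(freqs - pk$center)^2 / (2 * sigma^2))
      comp <- shaped_noise(n, fs, pk_psd * g)
      gain_env <- sqrt(unname(pk$stage_gain[t_stage]))
      if (length(wake_epochs)) {
        gain_env[epoch_of_sample %in% wake_epochs] <- 0
      }
      sig <- sig + comp * gain_env * drift_env
    }
    emg_rms_ch <- spec$emg_level * exp(stats::rnorm(1, 0, 0.1))
    emg <- shaped_noise(n, fs, emg_shape * emg_rms_ch^2) *
      emg_env[epoch_of_sample]
    emg_component_sq <- emg_component_sq + emg^2 / 19
    data[ch, ] <- sig + emg
  }

  onsets <- segment_onsets()
  emg_rms <- vapply(names(onsets), function(lab) {
    idx <- (onsets[[lab]] * fs + 1):((onsets[[lab]] + 60) * fs)
    sqrt(mean(emg_component_sq[idx]))
  }, 0)

  structure(list(
    subject_id = spec$subject_id,
    sampling_rate = fs,
    channels = eeg_channels(),
    data = data,
    stage_annotation = data.frame(
      onset = c(0, 300), duration = c(300, 600),
      stage = c("N1", "N2"), stringsAsFactors = FALSE
    ),
    emg_rms_by_segment = emg_rms
  ), class = "sleep_recording")
}

#' @export
print.sleep_recording <- function(x, ...) {
  cat(sprintf("<sleep_recording %s: %d ch x %d samples @ %g Hz (%g s)>\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}
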