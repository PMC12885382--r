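# Zero-phase band-pass via frequency-domain windowing: unit gain in
# [l_freq, h_freq], raised-cosine transitions of width `trans` on both
# sides, zero outside. Linear (zero) phase by construction.
fft_bandpass <- function(x, fs, l_freq = 1, h_freq = 45, trans = 0.5) {
  n <- length(x)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * fs / n
  af <- abs(f)
  resp <- numeric(n)
  resp[af >= l_freq & af <= h_freq] <- 1
  lo <- af > (l_freq - trans) & af < l_freq
  resp[lo] <- 0.5 * (1 - cos(pi * (af[lo] - (l_freq - trans)) / trans))
  hi <- af > h_freq & af < (h_freq + trans)
  resp[hi] <- 0.5 * (1 + cos(pi * (af[hi] - h_freq) / trans))
  Re(stats::fft(stats::fft(x) * resp, inverse = TRUE)) / n
}

#' Band-pass filter a recording and cut it into labeled 60-s epochs
#'
#' Applies a zero-phase 1-45 Hz band-pass (0.5 Hz raised-cosine
#' transitions) to every channel, then extracts the six analysis epochs:
#' two from the N1 block and four from the N2 block, labeled
#' N1a, N1b, N2a, N2b, N2c, N2d in chronological order. N1a/N1b sit at
#' the start and end of the 300-s N1 block; N2a/N2b are adjacent early
#' N2 epochs, N2c/N2d later ones.
#'
#' @param recording A `sleep_recording`.
#' @param l_freq,h_freq Band-pass edges in Hz.
#' @return List of six `eeg_epoch` objects (fields `data` 19 x 15000,
#'   `subject_id`, `segment_label`, `stage`, `onset`, `fs`).
#' @export
bandpass_and_epoch <- function(recording, l_freq = 1, h_freq = 45) {
  stopifnot(inherits(recording, "sleep_recording"))
  fs <- recording$sampling_rate
  nsamp <- ncol(recording$data)
  onsets <- segment_onsets()
  need <- max(onsets + 60) * fs
  if (nsamp < need) {
    stop(sprintf("recording of subject %s too short for 6 epochs (%g s < %g s)",
                 recording$subject_id, nsamp / fs, need / fs))
  }
  filt <- t(apply(recording$data, 1, fft_bandpass, fs = fs,
                  l_freq = l_freq, h_freq = h_freq))
  rownames(filt) <- recording$channels
  lapply(names(onsets), function(lab) {
    idx <- (onsets[[lab]] * fs + 1):((onsets[[lab]] + 60) * fs)
    structure(list(
      data = filt[, idx, drop = FALSE],
      subject_id = recording$subject_id,
      segment_label = lab,
      stage = segment_stage(lab),
      onset = onsets[[lab]],
      fs = fs
    ), class = "eeg_epoch")
  })
}
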