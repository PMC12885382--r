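#' Welch power spectral density of a 60-s epoch
#'
#' Welch's method with a Hamming window, 1024-sample segments and 50%
#' overlap at 250 Hz sampling, giving the fixed ~0.244 Hz frequency
#' grid (250/1024). One-sided density normalization: for a stationary
#' signal the integral of the PSD over frequency estimates the variance.
#'
#' @param epoch An `eeg_epoch` (from [bandpass_and_epoch()]) or a
#'   channels x samples matrix.
#' @param fs Sampling rate; must be 250 when `epoch` is a bare matrix
#'   (taken from the epoch otherwise).
#' @param nfft Window/FFT length (default 1024).
#' @return A `psd_segment`: list with `subject_id`, `segment_label`,
#'   `stage`, `freqs` (Hz), `psd` (channels x frequencies, uV^2/Hz).
#' @export
welch_psd <- function(epoch, fs = 250, nfft = 1024) {
  if (inherits(epoch, "eeg_epoch")) {
    x <- epoch$data
    fs <- epoch$fs
    meta <- epoch[c("subject_id", "segment_label", "stage")]
  } else {
    x <- as.matrix(epoch)
    meta <- list(subject_id = NA_character_, segment_label = NA_character_,
                 stage = NA_character_)
  }
  if (fs != 250) stop("`welch_psd` expects 250 Hz sampling")
  nsamp <- ncol(x)
  if (nsamp < nfft) stop("epoch shorter than one Welch window")
  step <- nfft %/% 2
  starts <- seq(1, nsamp - nfft + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))  # Hamming
  U <- sum(w^2)
  nh <- nfft %/% 2 + 1
  psd <- matrix(0, nrow = nrow(x), ncol = nh)
  for (ch in seq_len(nrow(x))) {
    segs <- vapply(starts, function(s0) x[ch, s0:(s0 + nfft - 1)] * w,
                   numeric(nfft))
    P <- abs(stats::mvfft(segs))^2
    avg <- rowMeans(P[seq_len(nh), , drop = FALSE])
    scale <- 2 / (fs * U)
    avg <- avg * scale
    avg[1] <- avg[1] / 2                     # DC not doubled
    if (nfft %% 2 == 0) avg[nh] <- avg[nh] / 2  # Nyquist not doubled
    psd[ch, ] <- avg
  }
  rownames(psd) <- rownames(x)
  structure(list(
    subject_id = meta$subject_id,
    segment_label = meta$segment_label,
    stage = meta$stage,
    freqs = (0:(nh - 1)) * fs / nfft,
    psd = psd
  ), class = "psd_segment")
}

#' @export
print.psd_segment <- function(x, ...) {
  cat(sprintf("<psd_segment %s/%s (%s): %d ch, %.3f Hz grid to %.1f Hz>\n",
              x$subject_id, x$segment_label, x$stage, nrow(x$psd),
              diff(x$freqs[1:2]), max(x$freqs)))
  invisible(x)
}
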