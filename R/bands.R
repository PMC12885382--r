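#' The 13 log-widening frequency bands
#'
#' Band widths start at 2 Hz and grow by exactly 0.2 Hz per band, tiling
#' 1-42.6 Hz: 1-3, 3-5.2, 5.2-7.6, 7.6-10.2, 10.2-13, 13-16, 16-19.2,
#' 19.2-22.6, 22.6-26.2, 26.2-30, 30-34, 34-38.2, 38.2-42.6 Hz. Bands are
#' half-open `[low, high)` so shared edges belong to the upper band.
#'
#' @return A `band_definition`: data.frame with columns `band`, `low`,
#'   `high`, `width`, plus attribute `edges` (the 14 boundaries).
#' @export
define_bands <- function() {
  widths <- 2 + 0.2 * (0:12)
  edges <- c(1, 1 + cumsum(widths))
  out <- data.frame(band = 1:13, low = edges[1:13], high = edges[2:14],
                    width = widths)
  attr(out, "edges") <- edges
  class(out) <- c("band_definition", "data.frame")
  out
}

# trapezoid integral of y(x) over [lo, hi], with linear interpolation at
# the interval endpoints; x must be sorted ascending and cover [lo, hi]
trapz_band <- function(x, y, lo, hi) {
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, lo)$y, y[inside], stats::approx(x, y, hi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)])) / 2
}

#' Relative bandpower features of one PSD segment
#'
#' Per channel, integrates the PSD over each of the 13 bands (trapezoid
#' rule on the Welch grid, interpolating at band edges) and divides by
#' the total power over the 13 bands (1-42.6 Hz), so the 13 values of a
#' channel sum to exactly 1. Features are channel-major: channel 1 bands
#' 1-13, channel 2 bands 1-13, and so on (s = 19 x 13 = 247).
#'
#' @param segment A `psd_segment` from [welch_psd()].
#' @param bands A [define_bands()] table.
#' @return Numeric vector of length `nchan * 13` (247 for 19 channels),
#'   named `<channel>.b<band>`.
#' @export
relative_bandpower <- function(segment, bands = define_bands()) {
  stopifnot(inherits(segment, "psd_segment"))
  freqs <- segment$freqs
  if (min(freqs) > bands$low[1] || max(freqs) < bands$high[13]) {
    stop("PSD grid does not cover 1-42.6 Hz")
  }
  psd <- segment$psd
  nchan <- nrow(psd)
  out <- numeric(nchan * 13)
  for (ch in seq_len(nchan)) {
    bp <- vapply(seq_len(13), function(b) {
      trapz_band(freqs, psd[ch, ], bands$low[b], bands$high[b])
    }, 0)
    tot <- sum(bp)
    if (tot <= 0) {
      stop(sprintf("degenerate channel %s: zero power in 1-42.6 Hz",
                   rownames(psd)[ch] %||% ch))
    }
    out[(ch - 1) * 13 + 1:13] <- bp / tot
  }
  names(out) <- paste0(rep(rownames(psd) %||% paste0("ch", seq_len(nchan)),
                           each = 13), ".b", rep(1:13, nchan))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the channel-averaged PSD curve
#'
#' Trapezoidal integral of the channel-mean PSD over 1-42.6 Hz; the
#' total-power summary used in the age regressions.
#'
#' @param segment A `psd_segment`.
#' @return Non-negative scalar (uV^2).
#' @export
psd_auc <- function(segment) {
  stopifnot(inherits(segment, "psd_segment"))
  avg <- colMeans(segment$psd)
  trapz_band(segment$freqs, avg, 1, 42.6)
}
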