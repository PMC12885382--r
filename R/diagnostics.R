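# --- single-chain split diagnostics (rank-normalized R-hat, Geyer ESS) ---

split_chain <- function(x) {
  n <- length(x) %/% 2
  cbind(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
}

rank_normalize <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) /
                 (length(x) + 1 / 4))
}

# chains: n x m matrix (columns = chains)
rhat_of_chains <- function(chains) {
  n <- nrow(chains); m <- ncol(chains)
  mu <- colMeans(chains)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(mu)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# per-chain autocovariance via FFT (biased, as in standard ESS estimators)
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, npad - n)))
  # ifft of the power spectrum gives the linear autocovariance sums
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / npad / n
}

ess_of_chains <- function(chains) {
  n <- nrow(chains); m <- ncol(chains)
  W <- mean(apply(chains, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  acov <- rowMeans(apply(chains, 2, autocov_fft)) * n / (n - 1)
  mu <- colMeans(chains)
  varplus <- (n - 1) / n * W + (if (m > 1) n * stats::var(mu) / n else 0)
  rho <- 1 - (W - acov) / varplus
  # Geyer initial monotone positive sequence over lag pairs
  tau <- 0
  last <- Inf
  t <- 1
  while (t + 1 < n) {
    pair <- rho[t + 1] + ifelse(t + 2 <= n, rho[t + 2], 0)
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, last)
    last <- pair
    tau <- tau + pair
    t <- t + 2
  }
  ess <- n * m / (1 + 2 * tau)
  min(ess, n * m * log10(n * m))   # cap antithetic estimates
}

#' Split R-hat of a single chain
#'
#' Rank-normalized potential scale-reduction factor computed between the
#' two halves of one chain.
#' @param x Numeric chain.
#' @return Scalar R-hat (NA for constant chains).
#' @export
split_rhat <- function(x) {
  z <- rank_normalize(x)
  rhat_of_chains(split_chain(z))
}

#' Bulk effective sample size of a single chain
#'
#' ESS of the rank-normalized split chain (sensitive to mixing in the
#' bulk of the distribution).
#' @param x Numeric chain.
#' @return Scalar ESS (NA for constant chains).
#' @export
ess_bulk <- function(x) {
  z <- rank_normalize(x)
  ess_of_chains(split_chain(z))
}

#' Tail effective sample size of a single chain
#'
#' Minimum of the split-chain ESS of the 5% and 95% quantile indicator
#' sequences (sensitive to mixing in the tails).
#' @param x Numeric chain.
#' @return Scalar ESS (NA for constant chains).
#' @export
ess_tail <- function(x) {
  qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
  ev <- vapply(qs, function(q) {
    ind <- as.numeric(x <= q)
    if (stats::var(ind) == 0) return(NA_real_)
    ess_of_chains(split_chain(rank_normalize(ind)))
  }, 0)
  if (all(is.na(ev))) NA_real_ else min(ev, na.rm = TRUE)
}

#' Convergence diagnostics for sampled coefficient entries
#'
#' Draws `n_entries` random positions of the reduced-rank coefficient
#' matrix `Theta = Psi Gamma`, reconstructs each entry's retained-draw
#' chain, and reports split R-hat plus bulk and tail ESS. Entries with
#' either ESS below `ess_min` (default 100, the usual rule of thumb for
#' accepting a sample) are flagged.
#'
#' @param posterior A `brrr_posterior` with >= 100 retained draws.
#' @param n_entries Number of random Theta entries (default 200).
#' @param seed Seed for the entry sample.
#' @param ess_min Flagging threshold.
#' @return data.frame (row, col, rhat, ess_bulk, ess_tail, flagged) with
#'   a `summary` attribute (mean and SD of each diagnostic).
#' @export
convergence_diagnostics <- function(posterior, n_entries = 200, seed = 1,
                                    ess_min = 100) {
  stopifnot(inherits(posterior, "brrr_posterior"))
  Tn <- dim(posterior$draws$Psi)[1]
  if (Tn < 4) stop("need at least 4 retained draws")
  if (Tn < 100) warning("fewer than 100 retained draws; diagnostics noisy")
  p <- dim(posterior$draws$Psi)[2]
  s <- dim(posterior$draws$Gamma)[3]
  set.seed(as.integer(seed))
  n_entries <- min(n_entries, p * s)
  pos <- sample.int(p * s, n_entries)
  rows <- ((pos - 1) %% p) + 1
  cols <- ((pos - 1) %/% p) + 1
  out <- data.frame(row = rows, col = cols, rhat = NA_real_,
                    ess_bulk = NA_real_, ess_tail = NA_real_)
  for (e in seq_len(n_entries)) {
    Pa <- matrix(posterior$draws$Psi[, rows[e], ], nrow = Tn)
    Ga <- matrix(posterior$draws$Gamma[, , cols[e]], nrow = Tn)
    th <- rowSums(Pa * Ga)
    out$rhat[e] <- split_rhat(th)
    out$ess_bulk[e] <- ess_bulk(th)
    out$ess_tail[e] <- ess_tail(th)
  }
  out$flagged <- is.na(out$ess_bulk) | is.na(out$ess_tail) |
    out$ess_bulk < ess_min | out$ess_tail < ess_min
  attr(out, "summary") <- c(
    rhat_mean = mean(out$rhat, na.rm = TRUE),
    rhat_sd = stats::sd(out$rhat, na.rm = TRUE),
    ess_bulk_mean = mean(out$ess_bulk, na.rm = TRUE),
    ess_bulk_sd = stats::sd(out$ess_bulk, na.rm = TRUE),
    ess_tail_mean = mean(out$ess_tail, na.rm = TRUE),
    ess_tail_sd = stats::sd(out$ess_tail, na.rm = TRUE),
    n_flagged = sum(out$flagged)
  )
  out
}
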