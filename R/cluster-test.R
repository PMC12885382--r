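# Per-frequency-bin one-way repeated-measures F across segment labels.
# M: (I*J) x F matrix with subject index fastest; returns F per bin.
rm_f_bins <- function(M, I, J) {
  i_idx <- rep(seq_len(I), times = J)
  j_idx <- rep(seq_len(J), each = I)
  grand <- colMeans(M)
  seg_mean <- rowsum(M, j_idx) / I          # J x F
  subj_mean <- rowsum(M, i_idx) / J         # I x F
  resid <- M - subj_mean[i_idx, , drop = FALSE] -
    seg_mean[j_idx, , drop = FALSE] + rep(grand, each = I * J)
  ss_seg <- I * colSums(sweep(seg_mean, 2, grand)^2)
  ss_err <- colSums(resid^2)
  ms_seg <- ss_seg / (J - 1)
  ms_err <- ss_err / ((I - 1) * (J - 1))
  # scale-aware floor so numerically-zero segment effects give F = 0
  # rather than 0/0 blow-ups, while genuinely error-free effects still
  # produce very large F
  ss_tot <- colSums((M - rep(grand, each = I * J))^2)
  ms_seg / pmax(ms_err, 1e-12 * ss_tot + .Machine$double.xmin)
}

# contiguous runs of TRUE -> data.frame(start, end)
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Cluster-level permutation test on per-subject spectra
#'
#' Tests whether a set of paired segments (e.g., the two N1 or four N2
#' analysis segments) differ in their channel-averaged PSDs anywhere
#' along frequency, with family-wise control across frequency bins.
#' Per bin, a one-way repeated-measures F statistic across segment
#' labels is computed; bins exceeding the `1 - alpha_cluster` quantile
#' of an F(d1, d2) reference form contiguous clusters whose mass is the
#' summed F. The null distribution of the maximum cluster mass comes
#' from within-subject permutations of the segment labels; cluster
#' p-values use the `(count + 1) / (n_perm + 1)` convention.
#'
#' @param psd_by_segment 3-d array, subjects x segments x frequency
#'   bins, of channel-averaged PSD values (every subject must have all
#'   segments).
#' @param d1,d2 Threshold df; defaults d1 = segments - 1 and, following
#'   the reported convention, d2 = number of subjects. Set
#'   `df_convention = "conventional"` for the usual error df
#'   `(I - 1)(J - 1)`.
#' @param alpha_cluster Cluster-forming threshold p (default 0.01).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Seed for the permutations.
#' @param freqs Optional frequency grid (Hz) for reporting cluster
#'   ranges in Hz.
#' @param df_convention `"printed"` (d2 = n subjects) or
#'   `"conventional"`.
#' @return A `cluster_result`: `clusters` (start, end, freq_low,
#'   freq_high, mass, p), `threshold_F`, `dfs`, `n_perm`, `f_obs`.
#' @export
cluster_permutation_test <- function(psd_by_segment, d1 = NULL, d2 = NULL,
                                     alpha_cluster = 0.01, n_perm = 1000,
                                     seed = 1, freqs = NULL,
                                     df_convention = c("printed",
                                                       "conventional")) {
  df_convention <- match.arg(df_convention)
  A <- psd_by_segment
  stopifnot(length(dim(A)) == 3)
  I <- dim(A)[1]; J <- dim(A)[2]; nf <- dim(A)[3]
  if (J < 2) stop("need at least 2 segments per subject")
  if (anyNA(A)) stop("unequal segment counts per subject (NAs present)")
  if (is.null(d1)) d1 <- J - 1
  if (is.null(d2)) d2 <- if (df_convention == "printed") I else
    (I - 1) * (J - 1)
  thr <- stats::qf(1 - alpha_cluster, d1, d2)

  M <- matrix(A, I * J, nf)   # subject index fastest
  f_obs <- rm_f_bins(M, I, J)
  obs_runs <- runs_of(f_obs > thr)
  masses <- if (nrow(obs_runs)) {
    vapply(seq_len(nrow(obs_runs)), function(r) {
      sum(f_obs[obs_runs$start[r]:obs_runs$end[r]])
    }, 0)
  } else numeric(0)

  set.seed(as.integer(seed))
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    # permute segment labels independently within each subject
    perms <- vapply(seq_len(I), function(i) sample.int(J), integer(J))
    pi_mat <- t(perms)                          # I x J: pi_i(j)
    src_row <- rep(seq_len(I), times = J) + (as.vector(pi_mat) - 1L) * I
    Fp <- rm_f_bins(M[src_row, , drop = FALSE], I, J)
    pr <- runs_of(Fp > thr)
    null_max[b] <- if (nrow(pr)) {
      max(vapply(seq_len(nrow(pr)), function(r) {
        sum(Fp[pr$start[r]:pr$end[r]])
      }, 0))
    } else 0
  }
  pvals <- vapply(masses, function(m) (sum(null_max >= m) + 1) / (n_perm + 1),
                  0)
  clusters <- data.frame(
    start = obs_runs$start, end = obs_runs$end,
    freq_low = if (is.null(freqs)) rep(NA_real_, nrow(obs_runs)) else
      freqs[obs_runs$start],
    freq_high = if (is.null(freqs)) rep(NA_real_, nrow(obs_runs)) else
      freqs[obs_runs$end],
    mass = masses, p = pvals)
  structure(list(clusters = clusters, threshold_F = thr,
                 dfs = c(d1 = d1, d2 = d2), n_permutations = n_perm,
                 f_obs = f_obs, freqs = freqs),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d cluster(s), F threshold %.2f (df %g, %g), %d perms>\n",
              nrow(x$clusters), x$threshold_F, x$dfs[1], x$dfs[2],
              x$n_permutations))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
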