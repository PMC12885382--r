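#' Mantel permutation test between two dissimilarity matrices
#'
#' Pearson correlation of the vectorized off-diagonal entries of two
#' subject-by-subject matrices, with significance from simultaneous
#' row/column permutations of the second matrix. Paired (possibly
#' asymmetric) matrices are symmetrized as `(M + t(M)) / 2` before the
#' upper triangle is vectorized. The test is one-sided for positive
#' association and p-values use the `(count + 1) / (n_perm + 1)`
#' convention, so the smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param D1,D2 `paired_distance_matrix` objects or square matrices in
#'   the same subject order (N >= 4).
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed.
#' @return List: `r` (observed correlation), `p`, `n_perm`,
#'   `perm_r` (the null draws).
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1) {
  V1 <- if (inherits(D1, "paired_distance_matrix")) D1$values else
    as.matrix(D1)
  V2 <- if (inherits(D2, "paired_distance_matrix")) D2$values else
    as.matrix(D2)
  if (inherits(D1, "paired_distance_matrix") &&
      inherits(D2, "paired_distance_matrix") &&
      !identical(D1$subject_order, D2$subject_order)) {
    stop("subject order mismatch between matrices")
  }
  n <- nrow(V1)
  stopifnot(ncol(V1) == n, all(dim(V2) == n))
  if (n < 4) stop("need at least 4 subjects for a Mantel test")
  S1 <- (V1 + t(V1)) / 2
  S2 <- (V2 + t(V2)) / 2
  ut <- upper.tri(S1)
  v1 <- S1[ut]
  if (stats::sd(v1) == 0 || stats::sd(S2[ut]) == 0) {
    stop("constant matrix: Mantel correlation undefined")
  }
  r_obs <- stats::cor(v1, S2[ut])
  set.seed(as.integer(seed))
  perm_r <- vapply(seq_len(n_perm), function(b) {
    pp <- sample.int(n)
    stats::cor(v1, S2[pp, pp][ut])
  }, 0)
  p <- (sum(perm_r >= r_obs) + 1) / (n_perm + 1)
  list(r = r_obs, p = p, n_perm = n_perm, perm_r = perm_r)
}
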