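#' Fisher-LDA initialization of the projection matrix
#'
#' Computes the top-K discriminant directions of the between- vs
#' within-subject scatter of `Y` (subjects as classes) and returns them
#' as rows of the initial k x s projection. The within-class scatter is
#' ridge-regularized (`ridge * trace(Sw)/s` added to the diagonal) so the
#' usual s > n and duplicate-segment regimes stay solvable. When K
#' exceeds the number of discriminant directions (classes - 1), the
#' remaining rows are filled with the top right-singular vectors of the
#' class-centered residual.
#'
#' @param Y A `feature_matrix` (>= 2 observations per subject overall).
#' @param X A `subject_design` aligned with `Y`.
#' @param K Number of directions.
#' @param ridge Relative ridge for the within-class scatter.
#' @return K x s numeric matrix (rows = directions, unit norm).
#' @export
init_lda <- function(Y, X, K, ridge = 1e-6) {
  Ym <- Y$values
  Xm <- X$values
  s <- ncol(Ym)
  p <- ncol(Xm)
  n <- nrow(Ym)
  stopifnot(nrow(Xm) == n, K >= 1)
  counts <- colSums(Xm)
  if (any(counts == 0)) stop("subject with no observations")
  class_means <- diag(1 / counts) %*% crossprod(Xm, Ym)     # p x s
  centered <- Ym - Xm %*% class_means                        # within-class
  Sw <- crossprod(centered)
  grand <- colMeans(Ym)
  Mb <- sweep(class_means, 2, grand)
  Sb <- crossprod(Mb * sqrt(counts))
  tr <- sum(diag(Sw))
  lambda <- ridge * (if (tr > 0) tr / s else 1)
  if (tr == 0) warning("singular within-class scatter; ridge-regularized")
  diag(Sw) <- diag(Sw) + lambda
  C <- chol(Sw)
  Ci <- backsolve(C, diag(s))
  B <- crossprod(Ci, Sb) %*% Ci
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  m <- min(K, p - 1, s)
  dirs <- Ci %*% eig$vectors[, seq_len(m), drop = FALSE]     # s x m
  if (K > m) {
    sv <- svd(centered, nu = 0, nv = min(K - m, min(dim(centered))))
    extra <- sv$v[, seq_len(min(K - m, ncol(sv$v))), drop = FALSE]
    dirs <- cbind(dirs, extra)
    while (ncol(dirs) < K) {  # pathological: pad with random directions
      v <- stats::rnorm(s)
      dirs <- cbind(dirs, v / sqrt(sum(v^2)))
    }
  }
  dirs <- apply(dirs, 2, function(v) v / sqrt(sum(v^2)))
  t(dirs)[seq_len(K), , drop = FALSE]
}
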