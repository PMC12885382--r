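#' Project observations into the latent space
#'
#' Computes latent coordinates `Y Gamma^+` where `Gamma^+` is the right
#' pseudo-inverse of the k x s projection: the least-squares
#' reconstruction coordinates of each observation in the latent basis.
#' A rank-deficient `Gamma` falls back to the minimum-norm solution
#' (SVD) with a warning.
#'
#' @param Y_new A `feature_matrix` (standardized with the training
#'   parameters for held-out data) or a bare matrix.
#' @param gamma k x s projection matrix (e.g., the posterior mean
#'   `Gamma` of a fit).
#' @return A `latent_projection`: list with `coords` (n x k),
#'   `row_meta`, `gamma_used`.
#' @export
project_latent <- function(Y_new, gamma) {
  Ym <- if (inherits(Y_new, "feature_matrix")) Y_new$values else
    as.matrix(Y_new)
  meta <- if (inherits(Y_new, "feature_matrix")) Y_new$row_meta else
    data.frame(subject_id = rownames(Ym) %||% as.character(seq_len(nrow(Ym))),
               segment_label = NA_character_, stage = NA_character_)
  k <- nrow(gamma)
  if (ncol(Ym) != ncol(gamma)) {
    stop(sprintf("feature dimension mismatch: Y has %d, gamma has %d",
                 ncol(Ym), ncol(gamma)))
  }
  GGt <- gamma %*% t(gamma)
  pinv <- tryCatch(t(gamma) %*% solve(GGt), error = function(e) NULL)
  if (is.null(pinv) || rcond(GGt) < 1e-12) {
    warning("rank-deficient gamma; using minimum-norm pseudo-inverse")
    sv <- svd(gamma)
    pos <- sv$d > max(dim(gamma)) * .Machine$double.eps * sv$d[1]
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  structure(list(
    coords = Ym %*% pinv,
    row_meta = meta,
    gamma_used = gamma
  ), class = "latent_projection")
}

#' @export
print.latent_projection <- function(x, ...) {
  cat(sprintf("<latent_projection: %d obs in k=%d latent dims>\n",
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}
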