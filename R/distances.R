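#' Paired distance / similarity matrix container
#'
#' @param values N x N matrix; entry (i, j) compares subject i's segment-a
#'   observation with subject j's segment-b observation, so the diagonal
#'   holds the self-pair statistics.
#' @param kind `"l1_distance"` or `"pearson_similarity"`.
#' @param subject_order Subject ids shared by rows and columns.
#' @param row_segments,col_segments Segment-label sets of the two sides.
#' @return A `paired_distance_matrix`.
#' @export
paired_distance_matrix <- function(values, kind, subject_order,
                                   row_segments = NULL, col_segments = NULL) {
  kind <- match.arg(kind, c("l1_distance", "pearson_similarity"))
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values),
            nrow(values) == length(subject_order))
  if (kind == "l1_distance" && any(values < 0)) {
    stop("negative entries in an L1 distance matrix")
  }
  if (kind == "pearson_similarity" && any(abs(values) > 1 + 1e-8)) {
    stop("Pearson similarities outside [-1, 1]")
  }
  structure(list(values = values, kind = kind,
                 subject_order = subject_order,
                 row_segments = row_segments, col_segments = col_segments),
            class = "paired_distance_matrix")
}

#' @export
print.paired_distance_matrix <- function(x, ...) {
  cat(sprintf("<paired_distance_matrix (%s): %d subjects, rows %s vs cols %s>\n",
              x$kind, nrow(x$values),
              paste(x$row_segments %||% "?", collapse = "+"),
              paste(x$col_segments %||% "?", collapse = "+")))
  invisible(x)
}

#' L1 distances between two latent projections
#'
#' `values[i, j] = sum_d |a[i, d] - b[j, d]|`, comparing every subject's
#' segment-a latent coordinates against every subject's segment-b
#' coordinates. L1 rather than Euclidean distance is used for its better
#' behavior in higher-dimensional spaces.
#'
#' @param proj_a,proj_b `latent_projection`s with one row per subject, in
#'   the same subject order and dimension.
#' @return A `paired_distance_matrix` of kind `"l1_distance"`.
#' @export
l1_distances <- function(proj_a, proj_b) {
  A <- if (inherits(proj_a, "latent_projection")) proj_a$coords else
    as.matrix(proj_a)
  B <- if (inherits(proj_b, "latent_projection")) proj_b$coords else
    as.matrix(proj_b)
  ids_a <- if (inherits(proj_a, "latent_projection"))
    proj_a$row_meta$subject_id else rownames(A)
  ids_b <- if (inherits(proj_b, "latent_projection"))
    proj_b$row_meta$subject_id else rownames(B)
  if (ncol(A) != ncol(B)) stop("latent dimensions differ")
  if (nrow(A) != nrow(B)) stop("subject counts differ")
  if (!is.null(ids_a) && !is.null(ids_b) && !identical(ids_a, ids_b)) {
    stop("subject order mismatch between projections")
  }
  n <- nrow(A)
  D <- matrix(0, n, n)
  for (d in seq_len(ncol(A))) {
    D <- D + abs(outer(A[, d], B[, d], "-"))
  }
  paired_distance_matrix(D, "l1_distance",
                         subject_order = ids_a %||%
                           as.character(seq_len(n)),
                         row_segments = attr(proj_a, "segments"),
                         col_segments = attr(proj_b, "segments"))
}

#' Pearson-correlation similarities between feature observations
#'
#' `values[i, j]` is the Pearson correlation between subject i's
#' segment-a feature vector and subject j's segment-b feature vector,
#' computed on the full feature space without dimensionality reduction
#' (the correlation-based fingerprinting baseline).
#'
#' @param Y_a,Y_b `feature_matrix` objects (or matrices) with one row
#'   per subject in the same order.
#' @return A `paired_distance_matrix` of kind `"pearson_similarity"`.
#' @export
correlation_similarities <- function(Y_a, Y_b) {
  A <- if (inherits(Y_a, "feature_matrix")) Y_a$values else as.matrix(Y_a)
  B <- if (inherits(Y_b, "feature_matrix")) Y_b$values else as.matrix(Y_b)
  ids_a <- if (inherits(Y_a, "feature_matrix")) Y_a$row_meta$subject_id else
    rownames(A)
  if (nrow(A) != nrow(B) || ncol(A) != ncol(B)) {
    stop("feature matrices must have matching dimensions")
  }
  sd_a <- apply(A, 1, stats::sd)
  sd_b <- apply(B, 1, stats::sd)
  bad <- which(sd_a == 0 | sd_b == 0)
  if (length(bad)) {
    stop("zero-variance feature row(s): ",
         paste(ids_a[bad] %||% bad, collapse = ", "))
  }
  C <- stats::cor(t(A), t(B))
  paired_distance_matrix(C, "pearson_similarity",
                         subject_order = ids_a %||%
                           as.character(seq_len(nrow(A))))
}
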