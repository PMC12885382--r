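#' Fingerprinting success rate of a paired matrix
#'
#' Row-wise nearest-neighbor identification: for each subject i the
#' predicted identity is the column with the minimum distance
#' (`l1_distance`) or maximum similarity (`pearson_similarity`) in row
#' i; the subject is correctly identified when that column is i itself.
#' Ties are broken toward the lowest column index with a warning.
#'
#' @param matrix A `paired_distance_matrix`.
#' @param symmetric Also score column-wise and average the two rates.
#' @return A `fingerprint_report`: `success_rate`, `n_subjects`,
#'   `per_subject_correct`, `method`, `kind`.
#' @export
success_rate <- function(matrix, symmetric = FALSE) {
  stopifnot(inherits(matrix, "paired_distance_matrix"))
  V <- matrix$values
  pick <- if (matrix$kind == "l1_distance") which.min else which.max
  score_dir <- function(M) {
    pred <- integer(nrow(M))
    tied <- FALSE
    for (i in seq_len(nrow(M))) {
      j <- pick(M[i, ])
      if (sum(M[i, ] == M[i, j]) > 1) tied <- TRUE
      pred[i] <- j
    }
    if (tied) warning("ties in nearest-neighbor search; lowest index used")
    pred == seq_len(nrow(M))
  }
  correct <- score_dir(V)
  rate <- mean(correct)
  if (symmetric) rate <- mean(c(rate, mean(score_dir(t(V)))))
  structure(list(
    success_rate = rate,
    n_subjects = nrow(V),
    per_subject_correct = correct,
    method = if (matrix$kind == "l1_distance") "brrr" else "correlation",
    kind = matrix$kind
  ), class = "fingerprint_report")
}

#' @export
print.fingerprint_report <- function(x, ...) {
  cat(sprintf("<fingerprint_report (%s): success rate %.3f over %d subjects>\n",
              x$method, x$success_rate, x$n_subjects))
  invisible(x)
}

#' Per-subject differentiability Z-scores
#'
#' For subject i, contrasts the self-pair statistic `d(a_i, b_i)`
#' against the mean and sample SD of that subject's statistics to all
#' others, `{d(a_i, b_j), j != i}`. For distances the Z-score is negated
#' so that larger values always mean a more discernible individual; for
#' similarities it is used as-is.
#'
#' @param matrix A `paired_distance_matrix` with N >= 3 subjects.
#' @return Named numeric vector of per-subject scores (NA with a warning
#'   where the others' SD is zero).
#' @export
differentiability <- function(matrix) {
  stopifnot(inherits(matrix, "paired_distance_matrix"))
  V <- matrix$values
  n <- nrow(V)
  if (n < 3) stop("need at least 3 subjects for differentiability")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    others <- V[i, -i]
    mu <- mean(others)
    sdv <- stats::sd(others)
    if (!is.finite(sdv) || sdv == 0) {
      warning(sprintf("zero SD of other-distances for subject %s",
                      matrix$subject_order[i]))
      scores[i] <- NA_real_
    } else {
      z <- (V[i, i] - mu) / sdv
      scores[i] <- if (matrix$kind == "l1_distance") -z else z
    }
  }
  names(scores) <- matrix$subject_order
  scores
}
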