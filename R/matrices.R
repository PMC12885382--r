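#' Construct a feature matrix with row metadata
#'
#' @param values n x s numeric matrix (rows = observations).
#' @param subject_id,segment_label,stage Per-row metadata vectors.
#' @return A `feature_matrix`: list with `values`, `row_meta`
#'   (data.frame), `standardized` flag and `standardization` parameters.
#' @export
feature_matrix <- function(values, subject_id, segment_label,
                           stage = segment_stage(segment_label)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(subject_id),
            nrow(values) == length(segment_label))
  structure(list(
    values = values,
    row_meta = data.frame(subject_id = subject_id,
                          segment_label = segment_label,
                          stage = stage, stringsAsFactors = FALSE),
    standardized = FALSE,
    standardization = NULL
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d obs x %d features, %d subjects%s>\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$row_meta$subject_id)),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

# one-hot subject design aligned to subject_order
subject_design_from_meta <- function(subject_id, subject_order) {
  n <- length(subject_id)
  p <- length(subject_order)
  idx <- match(subject_id, subject_order)
  if (anyNA(idx)) stop("subject id missing from subject_order")
  X <- matrix(0, n, p)
  X[cbind(seq_len(n), idx)] <- 1
  structure(list(values = X, subject_order = subject_order),
            class = "subject_design")
}

#' @export
print.subject_design <- function(x, ...) {
  cat(sprintf("<subject_design: %d obs x %d subjects>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Assemble response and design matrices from PSD segments
#'
#' Converts each PSD segment to its 247 relative-bandpower features and
#' stacks them into the response matrix `Y`, rows ordered by
#' (subject, segment label), with the one-hot subject indicator `X`.
#'
#' @param segments List of `psd_segment` objects.
#' @param segment_labels_used Labels to include (default
#'   [segment_labels()]); every subject must contribute each exactly once.
#' @param bands Band definition for [relative_bandpower()].
#' @return List with `Y` (`feature_matrix`) and `X` (`subject_design`).
#' @export
build_matrices <- function(segments, segment_labels_used = segment_labels(),
                           bands = define_bands()) {
  subj <- vapply(segments, `[[`, "", "subject_id")
  lab <- vapply(segments, `[[`, "", "segment_label")
  keep <- lab %in% segment_labels_used
  segments <- segments[keep]; subj <- subj[keep]; lab <- lab[keep]
  subjects <- sort(unique(subj))
  key <- paste(subj, lab)
  if (anyDuplicated(key)) {
    stop("duplicate segment label for subject(s): ",
         paste(unique(subj[duplicated(key)]), collapse = ", "))
  }
  want <- expand.grid(subject = subjects, label = segment_labels_used,
                      stringsAsFactors = FALSE)
  missing <- !(paste(want$subject, want$label) %in% key)
  if (any(missing)) {
    stop("missing segment(s) for subject(s): ",
         paste(unique(want$subject[missing]), collapse = ", "))
  }
  ord <- order(subj, match(lab, segment_labels_used))
  segments <- segments[ord]; subj <- subj[ord]; lab <- lab[ord]
  feats <- t(vapply(segments, relative_bandpower,
                    numeric(13 * nrow(segments[[1]]$psd)), bands = bands))
  Y <- feature_matrix(feats, subject_id = subj, segment_label = lab,
                      stage = vapply(segments, `[[`, "", "stage"))
  X <- subject_design_from_meta(subj, subjects)
  list(Y = Y, X = X)
}

#' Write / read a feature matrix as CSV
#'
#' The CSV holds the row metadata (subject_id, segment_label, stage)
#' followed by one column per feature; `read_feature_csv` rebuilds the
#' `feature_matrix` and its one-hot `subject_design`.
#'
#' @param Y A `feature_matrix`.
#' @param path CSV file path.
#' @return `write_feature_csv` returns `path` invisibly;
#'   `read_feature_csv` returns `list(Y, X)`.
#' @export
write_feature_csv <- function(Y, path) {
  stopifnot(inherits(Y, "feature_matrix"))
  utils::write.csv(cbind(Y$row_meta, as.data.frame(Y$values)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- c("subject_id", "segment_label", "stage")
  stopifnot(all(meta_cols %in% names(df)))
  vals <- as.matrix(df[setdiff(names(df), meta_cols)])
  Y <- feature_matrix(vals, subject_id = df$subject_id,
                      segment_label = df$segment_label, stage = df$stage)
  X <- subject_design_from_meta(df$subject_id, sort(unique(df$subject_id)))
  list(Y = Y, X = X)
}

#' Z-score features, optionally carrying parameters to held-out data
#'
#' Standardizes each column of `train` to zero mean and unit SD; when
#' `apply_to` is given it is transformed with the training parameters
#' (never its own), which is how test folds are handled in
#' cross-validation to avoid leakage.
#'
#' @param train A `feature_matrix` with >= 2 rows.
#' @param apply_to Optional second `feature_matrix`.
#' @param eps Variance floor substituted (with a warning) for
#'   zero-variance columns.
#' @return The standardized `train`, or (when `apply_to` is given) a
#'   list `train`/`applied`.
#' @export
zscore_features <- function(train, apply_to = NULL, eps = 1e-12) {
  stopifnot(inherits(train, "feature_matrix"), nrow(train$values) >= 2)
  mu <- colMeans(train$values)
  sdv <- apply(train$values, 2, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature column(s); using SD = %g",
                    sum(zero), sqrt(eps)))
    sdv[zero] <- sqrt(eps)
  }
  std <- function(fm) {
    fm$values <- sweep(sweep(fm$values, 2, mu), 2, sdv, "/")
    fm$standardized <- TRUE
    fm$standardization <- list(mean = mu, sd = sdv)
    fm
  }
  if (is.null(apply_to)) std(train)
  else list(train = std(train), applied = std(apply_to))
}
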