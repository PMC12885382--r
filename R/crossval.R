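# subset a feature_matrix by row index, keeping metadata aligned
fm_subset <- function(Y, idx) {
  out <- Y
  out$values <- Y$values[idx, , drop = FALSE]
  out$row_meta <- Y$row_meta[idx, , drop = FALSE]
  out
}

# the segment pair used for self-pair scoring: first two labels sharing
# a stage (falls back to the first two labels)
infer_pair_labels <- function(meta) {
  labs <- unique(meta$segment_label)
  stages <- segment_stage(labs)
  for (st in unique(stages)) {
    same <- labs[stages == st]
    if (length(same) >= 2) return(same[1:2])
  }
  labs[1:2]
}

# rows of Y for (subjects x one label), ordered by `subjects`
rows_for_label <- function(Y, subjects, label) {
  idx <- vapply(subjects, function(sid) {
    w <- which(Y$row_meta$subject_id == sid & Y$row_meta$segment_label == label)
    if (length(w) != 1) {
      stop(sprintf("segment %s missing (or duplicated) for subject %s",
                   label, sid))
    }
    w
  }, 0L)
  idx
}

# one observation-pair fingerprint: project both segments, L1 + report
l1_fingerprint <- function(Y_std, gamma, subjects, pair_labels) {
  ia <- rows_for_label(Y_std, subjects, pair_labels[1])
  ib <- rows_for_label(Y_std, subjects, pair_labels[2])
  pa <- project_latent(fm_subset(Y_std, ia), gamma)
  pb <- project_latent(fm_subset(Y_std, ib), gamma)
  D <- l1_distances(pa, pb)
  D$row_segments <- pair_labels[1]
  D$col_segments <- pair_labels[2]
  D
}

#' Cross-validated fingerprinting with the reduced-rank model
#'
#' Partitions subjects (not rows) into folds; per fold, Z-scores with
#' the training rows' parameters, fits the model on training subjects,
#' projects the held-out subjects' segment pair through the trained
#' projection, and scores L1 nearest-neighbor identification among the
#' held-out subjects only. Training PTVE is reported per fold.
#'
#' @param Y,X Unstandardized `feature_matrix` and `subject_design`.
#' @param config A [brrr_config()].
#' @param folds Number of folds (default 10; each fold needs >= 2
#'   subjects).
#' @param seed Seed for the fold assignment and per-fold sampler seeds.
#' @param pair_labels The two segment labels scored as the self pair
#'   (default: first two same-stage labels in `Y`).
#' @return List: `mean_success_rate`, `sd_success_rate`, `mean_ptve`,
#'   and `per_fold` (fold, n_test, success_rate, ptve).
#' @export
crossval_fingerprint <- function(Y, X, config = brrr_config(), folds = 10,
                                 seed = 1, pair_labels = NULL) {
  subjects <- X$subject_order
  p <- length(subjects)
  if (p < folds) stop("need at least as many subjects as folds")
  if (is.null(pair_labels)) pair_labels <- infer_pair_labels(Y$row_meta)
  set.seed(as.integer(seed))
  fold_of <- sample(rep(seq_len(folds), length.out = p))
  if (min(table(fold_of)) < 2) stop("a fold has fewer than 2 subjects")
  per_fold <- data.frame(fold = seq_len(folds), n_test = NA_real_,
                         success_rate = NA_real_, ptve = NA_real_)
  for (f in seq_len(folds)) {
    test_subj <- subjects[fold_of == f]
    train_subj <- subjects[fold_of != f]
    tr_idx <- which(Y$row_meta$subject_id %in% train_subj)
    te_idx <- which(Y$row_meta$subject_id %in% test_subj)
    z <- zscore_features(fm_subset(Y, tr_idx), fm_subset(Y, te_idx))
    Xtr <- subject_design_from_meta(z$train$row_meta$subject_id, train_subj)
    cfg <- config
    cfg$seed <- (as.integer(seed) * 1009L + f) %% .Machine$integer.max
    fit <- gibbs_fit(z$train, Xtr, cfg)
    D <- l1_fingerprint(z$applied, fit$posterior_mean$Gamma,
                        test_subj, pair_labels)
    per_fold$n_test[f] <- length(test_subj)
    per_fold$success_rate[f] <- success_rate(D)$success_rate
    per_fold$ptve[f] <- ptve(fit, z$train, Xtr)
  }
  list(mean_success_rate = mean(per_fold$success_rate),
       sd_success_rate = stats::sd(per_fold$success_rate),
       mean_ptve = mean(per_fold$ptve),
       per_fold = per_fold,
       pair_labels = pair_labels)
}

#' Whole-data fingerprinting, latent and correlation routes
#'
#' Fits the model on all subjects' rows (after Z-scoring) and
#' fingerprints the given segment pair with L1 distances in the latent
#' space; the correlation baseline scores the same pair on the full
#' feature space.
#'
#' @param Y,X Unstandardized matrices.
#' @param config A [brrr_config()].
#' @param pair_labels Segment pair (default inferred).
#' @param method `"brrr"`, `"correlation"`, or `"both"`.
#' @return List with per-method `fingerprint_report`s (each with a
#'   `differentiability` vector and `matrix` attached); BRRR entry also
#'   carries `ptve` and the fitted posterior.
#' @export
fingerprint_whole <- function(Y, X, config = brrr_config(),
                              pair_labels = NULL,
                              method = c("both", "brrr", "correlation")) {
  method <- match.arg(method)
  if (is.null(pair_labels)) pair_labels <- infer_pair_labels(Y$row_meta)
  subjects <- X$subject_order
  out <- list(pair_labels = pair_labels)
  Yz <- zscore_features(Y)
  if (method %in% c("both", "brrr")) {
    fit <- gibbs_fit(Yz, X, config)
    D <- l1_fingerprint(Yz, fit$posterior_mean$Gamma, subjects, pair_labels)
    rep <- success_rate(D)
    rep$differentiability <- differentiability(D)
    rep$ptve <- ptve(fit, Yz, X)
    rep$matrix <- D
    rep$fit <- fit
    out$brrr <- rep
  }
  if (method %in% c("both", "correlation")) {
    ia <- rows_for_label(Yz, subjects, pair_labels[1])
    ib <- rows_for_label(Yz, subjects, pair_labels[2])
    C <- correlation_similarities(fm_subset(Yz, ia), fm_subset(Yz, ib))
    C$row_segments <- pair_labels[1]
    C$col_segments <- pair_labels[2]
    rep <- success_rate(C)
    rep$differentiability <- differentiability(C)
    rep$matrix <- C
    out$correlation <- rep
  }
  out
}

#' Generalization of a trained latent space to new segments
#'
#' Projects two fingerprint segments per subject through a previously
#' trained projection (posterior-mean `Gamma`) and scores L1
#' identification, assessing whether the representation learned from
#' one segment set carries over to others. Held-out features are
#' standardized with the training parameters stored in the fit.
#'
#' @param fitted A `brrr_posterior`.
#' @param features Unstandardized `feature_matrix` containing the
#'   fingerprint segments for every training subject.
#' @param fingerprint_segments Length-2 label set to fingerprint on.
#' @param latent_train_segments Labels the fit was trained on (for the
#'   overlap flag; default from the fit's row metadata).
#' @return A `fingerprint_report` with `differentiability`, `matrix`,
#'   and `overlap` (TRUE when fingerprint segments intersect training
#'   segments).
#' @export
generalize <- function(fitted, features, fingerprint_segments,
                       latent_train_segments = NULL) {
  stopifnot(inherits(fitted, "brrr_posterior"),
            length(fingerprint_segments) == 2)
  if (is.null(latent_train_segments)) {
    latent_train_segments <- unique(fitted$row_meta$segment_label)
  }
  overlap <- any(fingerprint_segments %in% latent_train_segments)
  Yf <- features
  if (!is.null(fitted$standardization) && !Yf$standardized) {
    st <- fitted$standardization
    Yf$values <- sweep(sweep(Yf$values, 2, st$mean), 2, st$sd, "/")
    Yf$standardized <- TRUE
    Yf$standardization <- st
  }
  D <- l1_fingerprint(Yf, fitted$posterior_mean$Gamma,
                      fitted$subject_order, fingerprint_segments)
  rep <- success_rate(D)
  rep$differentiability <- differentiability(D)
  rep$matrix <- D
  rep$overlap <- overlap
  rep$train_segments <- latent_train_segments
  rep$test_segments <- fingerprint_segments
  rep
}

#' Success rate as a function of cohort size
#'
#' Subsamples subjects at each requested size and computes whole-data
#' success rates for both the latent (BRRR) and correlation methods,
#' tracing how identification difficulty grows with the number of
#' candidates.
#'
#' @param Y,X Unstandardized matrices.
#' @param sizes Cohort sizes to evaluate (each <= number of subjects).
#' @param replicates Subsample replicates per size.
#' @param seed Seed.
#' @param config A [brrr_config()].
#' @param pair_labels Segment pair (default inferred).
#' @return data.frame (size, replicate, method, success_rate).
#' @export
sweep_cohort_size <- function(Y, X, sizes, replicates = 1, seed = 1,
                              config = brrr_config(), pair_labels = NULL) {
  subjects <- X$subject_order
  if (any(sizes > length(subjects))) stop("size exceeds available subjects")
  if (is.null(pair_labels)) pair_labels <- infer_pair_labels(Y$row_meta)
  set.seed(as.integer(seed))
  rows <- list()
  for (sz in sizes) {
    for (r in seq_len(replicates)) {
      sub <- if (sz == length(subjects)) subjects else
        sort(sample(subjects, sz))
      idx <- which(Y$row_meta$subject_id %in% sub)
      Ys <- fm_subset(Y, idx)
      Xs <- subject_design_from_meta(Ys$row_meta$subject_id, sub)
      cfg <- config
      # full-cohort rows reproduce the plain whole-data rates exactly
      if (sz < length(subjects)) {
        cfg$seed <- (as.integer(seed) * 7919L + sz * 101L + r) %%
          .Machine$integer.max
      }
      fw <- fingerprint_whole(Ys, Xs, cfg, pair_labels, method = "both")
      rows[[length(rows) + 1]] <- data.frame(
        size = sz, replicate = r,
        method = c("brrr", "correlation"),
        success_rate = c(fw$brrr$success_rate,
                         fw$correlation$success_rate))
    }
  }
  do.call(rbind, rows)
}

#' Choose the latent dimension by the elbow of the success-rate curve
#'
#' Evaluates whole-data success rate and PTVE over a grid of latent
#' dimensions and picks the smallest K whose success-rate gain over the
#' previous grid point falls below `gain_threshold` (1 percentage point
#' by default) - the point of diminishing returns. The expected curve
#' shape is an inverse U: gains saturate near the true dimensionality
#' and large K eventually overfits.
#'
#' @param Y,X Unstandardized matrices.
#' @param k_grid Ascending integer grid of latent dimensions.
#' @param eval Optional callback `function(K)` returning
#'   `list(success_rate=, ptve=)`; default does whole-data BRRR
#'   fingerprinting at each K with `config`.
#' @param config Base [brrr_config()] for the default callback.
#' @param gain_threshold Elbow gain threshold on the success rate.
#' @return List: `chosen_k` and `curve` (data.frame K, success_rate,
#'   ptve).
#' @export
select_k_elbow <- function(Y, X, k_grid, eval = NULL,
                           config = brrr_config(), gain_threshold = 0.01) {
  if (length(k_grid) == 0) stop("empty k_grid")
  if (is.unsorted(k_grid)) stop("k_grid must be ascending")
  if (is.null(eval)) {
    eval <- function(K) {
      cfg <- config
      cfg$K <- K
      fw <- fingerprint_whole(Y, X, cfg, method = "brrr")
      list(success_rate = fw$brrr$success_rate, ptve = fw$brrr$ptve)
    }
  }
  res <- lapply(k_grid, eval)
  curve <- data.frame(K = k_grid,
                      success_rate = vapply(res, `[[`, 0, "success_rate"),
                      ptve = vapply(res, `[[`, 0, "ptve"))
  chosen <- k_grid[length(k_grid)]
  if (length(k_grid) >= 2) {
    gains <- diff(curve$success_rate)
    below <- which(gains < gain_threshold)
    if (length(below)) chosen <- k_grid[below[1] + 1]
  }
  list(chosen_k = chosen, curve = curve)
}
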