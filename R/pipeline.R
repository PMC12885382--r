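#' Attach per-segment EMG RMS columns to a cohort table
#'
#' @param cohort Cohort table from [generate_cohort()].
#' @param recordings List of `sleep_recording`s (same subjects).
#' @return The cohort table with `emg_<label>` columns added.
#' @export
cohort_with_emg <- function(cohort, recordings) {
  ids <- vapply(recordings, `[[`, "", "subject_id")
  stopifnot(setequal(ids, cohort$subject_id))
  m <- t(vapply(recordings, `[[`, numeric(6), "emg_rms_by_segment"))
  m <- m[match(cohort$subject_id, ids), , drop = FALSE]
  colnames(m) <- paste0("emg_", segment_labels())
  cbind(cohort, as.data.frame(m))
}

#' Simulate a cohort's recordings and extract PSD segments
#'
#' Runs the signal-level pipeline for every subject: simulate the
#' 900-s recording, band-pass and epoch it, and compute Welch PSDs of
#' the six analysis segments. Recordings are processed one subject at a
#' time and discarded, keeping memory flat.
#'
#' @param subjects List of `subject_spec`s from [generate_cohort()].
#' @param seed Base seed; subject i uses a derived sub-seed.
#' @return List: `segments` (list of `psd_segment`), `emg` (per-subject
#'   named RMS rows), `auc` (data.frame subject_id, segment_label,
#'   stage, auc).
#' @export
simulate_cohort_psd <- function(subjects, seed = 1) {
  segments <- list()
  emg <- matrix(NA_real_, length(subjects), 6,
                dimnames = list(NULL, segment_labels()))
  auc_rows <- list()
  for (i in seq_along(subjects)) {
    spec <- subjects[[i]]
    rec_seed <- (as.integer(seed) * 20011L + i * 37L) %% .Machine$integer.max
    rec <- simulate_recording(spec, seed = rec_seed)
    emg[i, ] <- rec$emg_rms_by_segment[segment_labels()]
    epochs <- bandpass_and_epoch(rec)
    for (ep in epochs) {
      ps <- welch_psd(ep)
      segments[[length(segments) + 1]] <- ps
      auc_rows[[length(auc_rows) + 1]] <- data.frame(
        subject_id = ps$subject_id, segment_label = ps$segment_label,
        stage = ps$stage, auc = psd_auc(ps), stringsAsFactors = FALSE)
    }
  }
  list(segments = segments,
       emg = emg,
       auc = do.call(rbind, auc_rows))
}

#' Default end-to-end run configuration
#'
#' All analysis defaults in one nested list: K = 30 latent dimensions,
#' 1000 Gibbs iterations with 500 burn-in, 10-fold cross-validation,
#' 999 Mantel permutations, 1000 cluster-test permutations, and the 13
#' standard bands.
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed for the run.
#' @param cohort [cohort_config()] overrides.
#' @param brrr [brrr_config()] overrides (list of fields).
#' @param fingerprint List: `pair_labels`, `folds`, `run_cv`.
#' @param stats List: `run`, `cluster_n_perm`, `mantel_n_perm`.
#' @param output_dir Optional directory for report and tables.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 30, seed = 1,
                       cohort = cohort_config(),
                       brrr = list(),
                       fingerprint = list(pair_labels = c("N2a", "N2b"),
                                          folds = 10, run_cv = FALSE),
                       stats = list(run = TRUE, cluster_n_perm = 1000,
                                    mantel_n_perm = 999),
                       output_dir = NULL) {
  bc <- brrr_config()
  for (nm in names(brrr)) bc[[nm]] <- brrr[[nm]]
  fp <- list(pair_labels = c("N2a", "N2b"), folds = 10, run_cv = FALSE)
  for (nm in names(fingerprint)) fp[[nm]] <- fingerprint[[nm]]
  st <- list(run = TRUE, cluster_n_perm = 1000, mantel_n_perm = 999)
  for (nm in names(stats)) st[[nm]] <- stats[[nm]]
  structure(list(n_subjects = n_subjects, seed = seed, cohort = cohort,
                 brrr = bc, fingerprint = fp, stats = st,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> features -> fit -> fingerprint -> group statistics.
#' Generates the cohort and recordings, extracts the 247 relative
#' bandpower features, fits the reduced-rank model, fingerprints the
#' configured segment pair with both the latent and correlation
#' methods, and (optionally) runs the group statistics: the Mantel test
#' between the two methods' dissimilarity matrices, the
#' differentiability regression, the cubic AUC-on-age regression, the
#' artifact-on-age regression, and a cluster permutation test on the N2
#' spectra. Fully deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @return A run report list (also written as JSON to
#'   `config$output_dir` when set).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  gen <- generate_cohort(config$n_subjects, seed = seed,
                         config = config$cohort)
  sim <- simulate_cohort_psd(gen$subjects, seed = seed)
  cohort <- gen$cohort
  cohort <- cbind(cohort, as.data.frame(sim$emg))
  names(cohort)[(ncol(cohort) - 5):ncol(cohort)] <-
    paste0("emg_", segment_labels())

  mats <- build_matrices(sim$segments)
  pair <- config$fingerprint$pair_labels
  cfg <- config$brrr
  cfg$seed <- (as.integer(seed) * 97L + 5L) %% .Machine$integer.max

  fw <- fingerprint_whole(mats$Y, mats$X, cfg, pair_labels = pair)
  report <- list(
    config = list(n_subjects = config$n_subjects, seed = seed,
                  K = cfg$K, n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                  pair_labels = pair),
    package_version = as.character(utils::packageVersion("sleepfp")),
    fingerprint = list(
      brrr_success_rate = fw$brrr$success_rate,
      correlation_success_rate = fw$correlation$success_rate,
      brrr_ptve = fw$brrr$ptve,
      brrr_mean_differentiability = mean(fw$brrr$differentiability,
                                         na.rm = TRUE),
      correlation_mean_differentiability =
        mean(fw$correlation$differentiability, na.rm = TRUE))
  )
  diag <- convergence_diagnostics(fw$brrr$fit, seed = seed)
  report$diagnostics <- as.list(attr(diag, "summary"))

  if (isTRUE(config$fingerprint$run_cv)) {
    cv <- crossval_fingerprint(mats$Y, mats$X, cfg,
                               folds = config$fingerprint$folds,
                               seed = seed, pair_labels = pair)
    report$cv <- list(mean_success_rate = cv$mean_success_rate,
                      sd_success_rate = cv$sd_success_rate,
                      mean_ptve = cv$mean_ptve)
  }

  if (isTRUE(config$stats$run)) {
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        sprintf("stage %s failed: %s", name, conditionMessage(e))
      })
    }
    noise <- emg_noise_covariate(cohort, pair[1], pair[2])
    dreg <- stage("differentiability_regression",
                  differentiability_regression(fw$brrr$differentiability,
                                               cohort, noise))
    auc_n1 <- sim$auc[sim$auc$segment_label == "N1a", ]
    auc_merged <- merge(auc_n1, cohort[c("subject_id", "age")],
                        by = "subject_id")
    areg <- stage("auc_age_regression",
                  auc_age_regression(auc_merged$auc, auc_merged$age))
    nreg <- stage("artifact_age_regression",
                  artifact_age_regression(noise, cohort$age[
                    match(noise$subject_id, cohort$subject_id)]))
    mt <- mantel_test(fw$brrr$matrix,
                      neg_similarity(fw$correlation$matrix),
                      n_perm = config$stats$mantel_n_perm,
                      seed = seed)
    # channel-averaged PSD array over the four N2 segments, 1-42.6 Hz
    arr <- psd_segment_array(sim$segments, c("N2a", "N2b", "N2c", "N2d"))
    cl <- cluster_permutation_test(arr$data, n_perm =
                                     config$stats$cluster_n_perm,
                                   seed = seed, freqs = arr$freqs)
    coefs_or_msg <- function(x) {
      if (inherits(x, "regression_result")) x$coefficients else x
    }
    report$stats <- list(
      mantel_r = mt$r, mantel_p = mt$p,
      differentiability_regression = coefs_or_msg(dreg),
      auc_age_regression = coefs_or_msg(areg),
      artifact_age_regression = coefs_or_msg(nreg),
      n2_clusters = cl$clusters)
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    utils::write.csv(cohort, file.path(config$output_dir, "cohort.csv"),
                     row.names = FALSE)
  }
  report
}

#' Write / read a run configuration as JSON
#'
#' The configuration round-trips exactly: `read_run_config(write_run_config(x))`
#' reproduces `x`.
#'
#' @param config A [run_config()].
#' @param path Output file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # config numerics are stored as doubles
  raw <- rapply(raw, function(v) if (is.integer(v)) as.numeric(v) else v,
                how = "replace")
  cfg <- run_config()
  for (nm in setdiff(names(raw), c("cohort", "brrr", "fingerprint",
                                   "stats", "output_dir"))) {
    cfg[[nm]] <- raw[[nm]]
  }
  cfg["output_dir"] <- list(raw$output_dir)   # keeps NULL as an element
  for (nm in names(raw$cohort)) cfg$cohort[[nm]] <- raw$cohort[[nm]]
  for (nm in names(raw$brrr)) cfg$brrr[[nm]] <- raw$brrr[[nm]]
  for (nm in names(raw$fingerprint)) {
    cfg$fingerprint[[nm]] <- raw$fingerprint[[nm]]
  }
  for (nm in names(raw$stats)) cfg$stats[[nm]] <- raw$stats[[nm]]
  cfg
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

# dissimilarity view of a similarity matrix (for Mantel comparisons)
neg_similarity <- function(pdm) {
  stopifnot(pdm$kind == "pearson_similarity")
  1 - pdm$values
}

# stack channel-averaged PSDs (restricted to 1-42.6 Hz) into a
# subjects x segments x bins array
psd_segment_array <- function(segments, labels) {
  subj <- vapply(segments, `[[`, "", "subject_id")
  lab <- vapply(segments, `[[`, "", "segment_label")
  subjects <- sort(unique(subj))
  freqs <- segments[[1]]$freqs
  keep <- freqs >= 1 & freqs <= 42.6
  arr <- array(NA_real_, c(length(subjects), length(labels), sum(keep)))
  for (ii in seq_along(subjects)) {
    for (jj in seq_along(labels)) {
      w <- which(subj == subjects[ii] & lab == labels[jj])
      if (length(w) != 1) stop("missing segment in psd_segment_array")
      arr[ii, jj, ] <- colMeans(segments[[w]]$psd)[keep]
    }
  }
  list(data = arr, freqs = freqs[keep], subjects = subjects,
       labels = labels)
}
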