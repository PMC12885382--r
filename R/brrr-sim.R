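#' Simulate feature data directly from the reduced-rank generative model
#'
#' Draws `Y = (X Psi + Omega) Gamma + E` with known ground-truth
#' parameters, for sampler recovery tests and calibration studies.
#' `X` is the one-hot subject indicator with `segments_per_subject`
#' rows per subject; rows of the latent noise `Omega` are i.i.d.
#' `N(0, latent_sd^2)`, residuals `E` i.i.d. `N(0, residual_sd^2)`.
#' `Psi` entries are standard normal; `Gamma` rows are standard normal
#' scaled by a geometrically decreasing factor so latent components are
#' ordered by importance, as the shrinkage prior assumes.
#'
#' @param n_subjects Number of subjects p.
#' @param segments_per_subject Observations per subject (>= 2).
#' @param s Feature dimension.
#' @param k_true True latent rank (<= min(n_subjects, s)).
#' @param noise_scales Length-2 numeric: (latent sd, residual sd).
#' @param seed Integer seed.
#' @param gamma_decay Per-component geometric scale decay of `Gamma`
#'   rows (1 = none).
#' @param psi_sd SD of the subject-effect entries; 0 gives an
#'   exchangeable null cohort with no subject signal.
#' @return List with `Y` (a `feature_matrix`), `X` (a `subject_design`),
#'   and `truth` (list Psi, Gamma, Omega, Sigma, Theta with
#'   `Theta = Psi %*% Gamma`).
#' @export
simulate_from_brrr <- function(n_subjects, segments_per_subject, s, k_true,
                               noise_scales = c(0.1, 0.5), seed = 1,
                               gamma_decay = 0.9, psi_sd = 1) {
  if (segments_per_subject < 2) stop("`segments_per_subject` must be >= 2")
  if (k_true > min(n_subjects, s)) {
    stop("`k_true` must be <= min(n_subjects, s)")
  }
  set.seed(as.integer(seed))
  p <- n_subjects
  m <- segments_per_subject
  n <- p * m
  latent_sd <- noise_scales[1]
  residual_sd <- noise_scales[2]

  Psi <- matrix(stats::rnorm(p * k_true, 0, psi_sd), p, k_true)
  Gamma <- matrix(stats::rnorm(k_true * s), k_true, s) *
    gamma_decay^(seq_len(k_true) - 1)
  Omega <- matrix(stats::rnorm(n * k_true, 0, latent_sd), n, k_true)
  E <- matrix(stats::rnorm(n * s, 0, residual_sd), n, s)

  subj_ids <- sprintf("S%04d", seq_len(p))
  subj_of_row <- rep(seq_len(p), each = m)
  X <- matrix(0, n, p)
  X[cbind(seq_len(n), subj_of_row)] <- 1

  Y <- (X %*% Psi + Omega) %*% Gamma + E
  seg_labels <- rep(sprintf("seg%d", seq_len(m)), times = p)

  Yfm <- feature_matrix(Y,
                        subject_id = subj_ids[subj_of_row],
                        segment_label = seg_labels,
                        stage = rep(NA_character_, n))
  Xsd <- subject_design_from_meta(Yfm$row_meta$subject_id, subj_ids)
  truth <- list(Psi = Psi, Gamma = Gamma, Omega = Omega,
                Sigma = rep(residual_sd^2, s),
                Theta = Psi %*% Gamma)
  list(Y = Yfm, X = Xsd, truth = truth)
}
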