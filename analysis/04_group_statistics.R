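#!/usr/bin/env Rscript
# Group-level statistics on the simulated cohort.
#
# (i) cluster-level permutation test on the four N2 spectra per subject;
# (ii) Mantel test between the latent-space and correlation
#      dissimilarity structures of the cohort;
# (iii) regression of differentiability scores on EMG noise, sex, age
#       and cap size; cubic regression of PSD AUC on age (robust SEs);
#       linear regression of artifact load on age.
# Writes clusters.csv, mantel.csv, regression_*.csv under results/.

library(sleepfp)

seed <- 2026
dat <- read_feature_csv("results/features.csv")
cohort <- read.csv("results/cohort.csv", stringsAsFactors = FALSE)
auc <- read.csv("results/auc.csv", stringsAsFactors = FALSE)
psd_n2 <- read.csv("results/psd_n2.csv", stringsAsFactors = FALSE)
psd_n1 <- read.csv("results/psd_n1.csv", stringsAsFactors = FALSE)

psd_array <- function(psd, labels) {
  subjects <- sort(unique(psd$subject_id))
  freqs <- sort(unique(psd$freq))
  A <- array(NA_real_, c(length(subjects), length(labels), length(freqs)))
  for (i in seq_along(subjects)) for (j in seq_along(labels)) {
    rows <- psd$subject_id == subjects[i] & psd$segment_label == labels[j]
    A[i, j, ] <- psd$psd[rows][order(psd$freq[rows])]
  }
  list(A = A, freqs = freqs, subjects = subjects)
}

## within-stage stability: do the four N2 segments differ anywhere? ----
n2 <- psd_array(psd_n2, c("N2a", "N2b", "N2c", "N2d"))
cl <- cluster_permutation_test(n2$A, n_perm = 1000, seed = seed,
                               freqs = n2$freqs)
message(sprintf("N2 within-stage cluster test: %d cluster(s); min p = %s",
                nrow(cl$clusters),
                if (nrow(cl$clusters)) format(min(cl$clusters$p)) else "-"))
write.csv(cl$clusters, "results/clusters.csv", row.names = FALSE)

## stage contrast: subject-average N1 vs N2 spectra --------------------
n1 <- psd_array(psd_n1, c("N1a", "N1b"))
stage <- array(NA_real_, c(length(n2$subjects), 2, length(n2$freqs)))
stage[, 1, ] <- apply(n1$A, c(1, 3), mean)
stage[, 2, ] <- apply(n2$A, c(1, 3), mean)
cls <- cluster_permutation_test(stage, n_perm = 1000, seed = seed,
                                freqs = n2$freqs)
if (nrow(cls$clusters)) {
  top <- cls$clusters[which.min(cls$clusters$p), ]
  message(sprintf(
    "N1-vs-N2 stage contrast: strongest cluster %.1f-%.1f Hz (p = %.3f)",
    top$freq_low, top$freq_high, top$p))
} else message("N1-vs-N2 stage contrast: no clusters")
write.csv(cls$clusters, "results/clusters_stage.csv", row.names = FALSE)

## Mantel between the two dissimilarity structures ---------------------
cfg <- brrr_config(K = 10, n_iter = 400, burn_in = 200, seed = seed)
fw <- fingerprint_whole(dat$Y, dat$X, cfg, pair_labels = c("N2a", "N2b"))
mt <- mantel_test(fw$brrr$matrix, 1 - fw$correlation$matrix$values,
                  n_perm = 999, seed = seed)
message(sprintf("Mantel (BRRR vs correlation dissimilarity): r = %.2f, p = %.3f",
                mt$r, mt$p))
write.csv(data.frame(r = mt$r, p = mt$p, n_perm = mt$n_perm),
          "results/mantel.csv", row.names = FALSE)

## regressions ----------------------------------------------------------
noise <- emg_noise_covariate(cohort, "N2a", "N2b")
dreg <- differentiability_regression(fw$brrr$differentiability, cohort,
                                     noise)
print(dreg)
write.csv(dreg$coefficients, "results/regression_differentiability.csv",
          row.names = FALSE)

auc_n1 <- merge(auc[auc$segment_label == "N1a", ],
                cohort[c("subject_id", "age")], by = "subject_id")
areg <- auc_age_regression(auc_n1$auc, auc_n1$age)
print(areg)
write.csv(areg$coefficients, "results/regression_auc_age.csv",
          row.names = FALSE)

nreg <- artifact_age_regression(noise, cohort$age[
  match(noise$subject_id, cohort$subject_id)])
print(nreg)
write.csv(nreg$coefficients, "results/regression_artifact_age.csv",
          row.names = FALSE)
message("Wrote results/clusters.csv, clusters_stage.csv, mantel.csv, regression_*.csv")
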