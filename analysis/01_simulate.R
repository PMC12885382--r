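#!/usr/bin/env Rscript
# Simulate the study cohort and extract its spectral features.
#
# Generates a 30-subject pediatric cohort with strong, stable
# per-subject spectral idiosyncrasies, simulates each subject's 900-s
# 19-channel recording (300 s N1 + 600 s N2), band-passes at 1-45 Hz,
# cuts the six 60-s analysis segments, and computes Welch PSDs and the
# 247 relative-bandpower features. Writes, under results/:
#   cohort.csv    subject covariates incl. per-segment EMG RMS
#   features.csv  247 features per (subject, segment) row
#   auc.csv       PSD area under the curve per segment
#   psd_n2.csv    channel-averaged N2 spectra (for 04_group_statistics)

library(sleepfp)

seed <- 2026
n_subjects <- 30
dir.create("results", showWarnings = FALSE)

message("Simulating ", n_subjects, "-subject cohort (seed ", seed, ") ...")
gen <- generate_cohort(n_subjects, seed = seed,
                       config = cohort_config_high_idiosyncrasy())
sim <- simulate_cohort_psd(gen$subjects, seed = seed)

cohort <- gen$cohort
emg <- as.data.frame(sim$emg)
names(emg) <- paste0("emg_", segment_labels())
cohort <- cbind(cohort, emg)
write.csv(cohort, "results/cohort.csv", row.names = FALSE)

mats <- build_matrices(sim$segments)
feat <- cbind(mats$Y$row_meta, as.data.frame(mats$Y$values))
write.csv(feat, "results/features.csv", row.names = FALSE)
write.csv(sim$auc, "results/auc.csv", row.names = FALSE)

save_psd_long <- function(labels, path) {
  arr <- sleepfp:::psd_segment_array(sim$segments, labels)
  psd_long <- do.call(rbind, lapply(seq_along(arr$subjects), function(i) {
    do.call(rbind, lapply(seq_along(arr$labels), function(j) {
      data.frame(subject_id = arr$subjects[i],
                 segment_label = arr$labels[j],
                 freq = arr$freqs, psd = arr$data[i, j, ])
    }))
  }))
  write.csv(psd_long, path, row.names = FALSE)
}
save_psd_long(c("N2a", "N2b", "N2c", "N2d"), "results/psd_n2.csv")
save_psd_long(c("N1a", "N1b"), "results/psd_n1.csv")

message(sprintf("Cohort: ages %.1f-%.1f y (median %.1f), %d F / %d M",
                min(cohort$age), max(cohort$age), median(cohort$age),
                sum(cohort$sex == "F"), sum(cohort$sex == "M")))
message(sprintf("Feature matrix: %d rows x %d features",
                nrow(mats$Y$values), ncol(mats$Y$values)))
message("Wrote results/cohort.csv, features.csv, auc.csv, psd_n1.csv, psd_n2.csv")
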