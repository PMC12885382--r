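#!/usr/bin/env Rscript
# Fingerprinting: whole-data and cross-validated subject identification.
#
# Compares the latent-space (L1) route against correlation-based
# fingerprinting on the full feature space, within N2 sleep (N2a+N2b),
# within N1 (N1a+N1b), on far-apart N2 segments (N2a+N2d), and across
# stages (N1a+N2b); then 10-fold cross-validation and generalization of
# the N2a+N2b latent space to the held-out N2c+N2d segments. Writes
#   fingerprint_tasks.csv  success rates and mean differentiability
#   cv_folds.csv           per-fold CV results

library(sleepfp)

seed <- 2026
dat <- read_feature_csv("results/features.csv")
cfg <- brrr_config(K = 10, n_iter = 400, burn_in = 200, seed = seed)

tasks <- list(c("N2a", "N2b"), c("N1a", "N1b"), c("N2a", "N2d"),
              c("N1a", "N2b"))
rows <- list()
fits <- list()
for (pair in tasks) {
  fw <- fingerprint_whole(dat$Y, dat$X, cfg, pair_labels = pair)
  task <- paste(pair, collapse = "+")
  fits[[task]] <- fw
  rows[[task]] <- data.frame(
    task = task,
    method = c("brrr", "correlation"),
    success_rate = c(fw$brrr$success_rate, fw$correlation$success_rate),
    mean_differentiability = c(mean(fw$brrr$differentiability, na.rm = TRUE),
                               mean(fw$correlation$differentiability,
                                    na.rm = TRUE)),
    ptve = c(fw$brrr$ptve, NA))
  message(sprintf("%-8s  BRRR SR %.2f (PTVE %.2f) | corr SR %.2f", task,
                  fw$brrr$success_rate, fw$brrr$ptve,
                  fw$correlation$success_rate))
}

message("10-fold cross-validation on N2a+N2b ...")
cv <- crossval_fingerprint(dat$Y, dat$X, cfg, folds = 10, seed = seed,
                           pair_labels = c("N2a", "N2b"))
message(sprintf("CV success rate %.2f +- %.2f, training PTVE %.2f",
                cv$mean_success_rate, cv$sd_success_rate, cv$mean_ptve))

gen <- generalize(fits[["N2a+N2b"]]$brrr$fit, dat$Y, c("N2c", "N2d"))
message(sprintf("N2a+N2b latent space fingerprinting N2c+N2d: SR %.2f",
                gen$success_rate))
rows[["gen"]] <- data.frame(task = "N2c+N2d (latent from N2a+N2b)",
                            method = "brrr",
                            success_rate = gen$success_rate,
                            mean_differentiability =
                              mean(gen$differentiability, na.rm = TRUE),
                            ptve = NA)

write.csv(do.call(rbind, rows), "results/fingerprint_tasks.csv",
          row.names = FALSE)
write.csv(cv$per_fold, "results/cv_folds.csv", row.names = FALSE)
message("Wrote results/fingerprint_tasks.csv, cv_folds.csv")
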