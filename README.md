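# sleepfp — sleep-EEG fingerprinting with latent-noise reduced-rank regression

Children's sleep EEG carries stable, individual-specific spectral
signatures: given two 60-second segments of light non-REM sleep per
child, a held-out segment can be matched to its owner among dozens of
candidates from the spatial-spectral profile alone. `sleepfp` is an R
package plus analysis workflow for studying such *neural fingerprints*
in 19-channel pediatric sleep EEG. It is aimed at researchers in
computational neurophysiology and biostatistics who want a tested,
fully reproducible implementation of the modeling pipeline — from raw
multichannel signal to group-level statistics — that runs end-to-end on
synthetic cohorts with known ground truth (clinical EEG cohorts cannot
be redistributed).

## The model

Relative bandpower features (19 channels × 13 log-widening bands between
1 and 42.6 Hz, s = 247 features per 60-s segment) are modeled with a
latent-noise Bayesian reduced-rank regression (BRRR):

    Y = (X Ψ + Ω) Γ + E

where `Y` (n × s) stacks the segments' features, `X` (n × p) is the
one-hot subject indicator, `Ψ` (p × k) holds subject effects in a
k-dimensional latent space, `Γ` (k × s) projects that space onto the
features, `Ω` (n × k) is latent noise sharing the projection with the
signal, and `E` has independent Gaussian entries with feature-specific
variances. The coefficient matrix `Θ = ΨΓ` is constrained to rank
k ≪ p, s; a multiplicative gamma-process shrinkage prior on `Γ`'s rows
orders the latent components by importance. Fitting is by Gibbs
sampling (conjugate updates throughout; the `Ψ` update marginalizes `Ω`
for fast mixing), initialized from Fisher-LDA discriminant directions.
Model fit is summarized by PTVE = Tr Cov(XΨΓ) / Tr Cov(Y).

Subjects are identified by nearest-neighbor matching: minimum L1
distance between segment projections `Y Γ⁺` in the latent space (BRRR
route), or maximum Pearson correlation on the full 247 features
(correlation baseline). Per-subject *differentiability* is the Z-score
of the self-pair distance against that subject's distances to everyone
else. Group-level statistics include cluster-level permutation tests on
spectra, Mantel tests between dissimilarity matrices, and covariate
regressions (EMG artifact load, sex, age, cap size) on
differentiability.

## Worked example

Simulate a 20-subject cohort with strong per-subject spectral
idiosyncrasies, extract features, fit the model, and fingerprint the
two adjacent N2 segments:

```r
library(sleepfp)

gen  <- generate_cohort(20, seed = 42,
                        config = cohort_config_high_idiosyncrasy())
sim  <- simulate_cohort_psd(gen$subjects, seed = 42)
mats <- build_matrices(sim$segments)
mats$Y
#> <feature_matrix: 120 obs x 247 features, 20 subjects>

fw <- fingerprint_whole(mats$Y, mats$X,
                        brrr_config(K = 10, n_iter = 400, burn_in = 200,
                                    seed = 9),
                        pair_labels = c("N2a", "N2b"))
fw$brrr$success_rate        # fraction of subjects whose own N2b segment
#> [1] 0.9                 # is the nearest latent-space match
fw$brrr$ptve                # share of feature variance explained by
#> [1] 0.9164464           # the subject-driven low-rank mean
fw$correlation$success_rate # full-feature correlation baseline
#> [1] 0.95
round(mean(fw$brrr$differentiability), 2)   # mean self-vs-others Z-score
#> [1] 2.17
```

A success rate of 0.9 means 18 of the 20 subjects were correctly
re-identified from their held-out segment; differentiability ≈ 2.2
means a typical subject's own segment is about two standard deviations
closer to them than other subjects' segments are.

The `analysis/` directory holds the full numbered workflow
(`01_simulate.R` … `05_k_sweep.R`): cohort simulation, model fit with
convergence diagnostics, the four fingerprinting tasks plus 10-fold
cross-validation and cross-segment generalization, group statistics,
and the latent-dimension / cohort-size sweeps. Each script reads and
writes plain CSV under `results/`. On the default 30-subject cohort the
fitted model reaches PTVE ≈ 0.90 with cross-validated success rate 1.0
on adjacent N2 segments, the stage contrast localizes to the sleep
spindle band, and the success-rate curve over K rises to a maximum near
the effective signal rank before collapsing under overfitting.

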