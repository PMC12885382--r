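Package: sleepfp
Title: Sleep-EEG Fingerprinting with Latent-Noise Bayesian Reduced-Rank Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-subject pediatric sleep-EEG cohorts, extracts
    relative bandpower features from Welch power spectra of N1/N2 sleep
    segments, and fits a latent-noise Bayesian reduced-rank regression
    (BRRR) by Gibbs sampling to obtain low-dimensional representations
    that differentiate individuals. Provides fingerprinting success rates
    and differentiability Z-scores for both the BRRR latent space (L1
    distances) and a correlation-based baseline, 10-fold cross-validation,
    cross-stage generalization, and group-level statistics: cluster-based
    permutation tests on power spectra, Mantel tests on dissimilarity
    matrices, and covariate regressions on differentiability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
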