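---
title: "Sleep-EEG fingerprinting with latent-noise reduced-rank regression"
author: "sleepfp authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Individual brains leave recognizable traces in their electrophysiology:
the spatial-spectral profile of a person's EEG is stable enough within a
recording session that a held-out data segment can often be matched to
its owner among dozens or hundreds of candidates. `sleepfp` implements
this *fingerprinting* analysis for pediatric sleep EEG: 19-channel
recordings spanning 900 s of light non-REM sleep (300 s labeled N1
followed by 600 s labeled N2), summarized as relative bandpower features
of six 60-s segments per subject, and modeled with a latent-noise
Bayesian reduced-rank regression (BRRR) whose low-dimensional projection
is learned to separate individuals.

Because clinical EEG cohorts cannot be redistributed, the package ships
a synthetic-cohort generator that reproduces the structural features the
analysis relies on, so every claim the package makes is testable
end-to-end on data with known ground truth.

# The model

For $n$ observations (segments) of $s$ features from $p$ subjects,

$$\mathbf{Y}_{n\times s} =
  (\mathbf{X}_{n\times p}\Psi_{p\times k} + \Omega_{n\times k})
  \Gamma_{k\times s} + \mathbf{E}_{n\times s},$$

where $\mathbf{X}$ is the one-hot subject indicator, $\Psi$ holds the
subject effects in a $k$-dimensional latent space, $\Gamma$ projects the
latent space onto the feature space, $\Omega$ is *latent noise* —
structured noise that enters through the same projection as the signal —
and $\mathbf{E}$ has independent Gaussian entries with feature-specific
variances $\Sigma$. The product $\Theta = \Psi\Gamma$ is the ordinary
regression coefficient matrix; the factorization constrains it to rank
$k \ll p, s$. Sharing $\Gamma$ between signal and latent noise encodes
the assumption that nuisance variation and subject effects live on the
same correlated feature subspace, which is what makes the model robust
when the noise is not independent across features.

Model fit is summarized by the proportion of total variance explained,

$$\mathrm{PTVE} =
  \frac{\mathrm{Tr}\,\mathrm{Cov}(\mathbf{X}\Psi\Gamma)}
       {\mathrm{Tr}\,\mathrm{Cov}(\mathbf{Y})},$$

the share of response variance carried by the subject-driven low-rank
mean, excluding the latent noise.

## Priors and sampler

Given all other blocks the model is linear-Gaussian, so the sampler is
a pure Gibbs scheme:

* $\Psi$ rows: Gaussian prior (SD `psi_prior_sd`, default 1), conjugate
  normal update. The latent noise is **marginalized out** of this step
  (via the Woodbury identity), which removes the strong $\Psi$–$\Omega$
  coupling and is the difference between chains that pass effective-
  sample-size rules of thumb at 1000 iterations and chains that do not.
* $\Omega$ rows: $\mathcal{N}(0, \sigma_\Omega^2 I)$ with
  $\sigma_\Omega = 0.1$ by default (variance 0.01, configurable): the
  latent noise is assumed small relative to the subject effects, which
  are free to explain most of the variance.
* $\Gamma$: column-wise (per feature) conjugate updates under a
  multiplicative gamma-process shrinkage prior on its rows
  ($a_1 = 2.1$, $a_2 = 3.1$, local prior df $\nu = 3$): expected
  precision of row $h$ grows with $h$, ordering the latent components
  by importance and suppressing unneeded ones. Any prior that enforces
  ordered column shrinkage would serve; this one keeps every update
  conjugate.
* $\Sigma$: inverse-gamma (shape/rate 1) updates from residuals.

Chains start from Fisher-LDA discriminant directions (ridge-regularized
within-class scatter, ridge $10^{-6}\,\mathrm{tr}(S_w)/s$) with $\Psi$
set to projected class means; if $K$ exceeds the number of discriminant
directions, the remainder is filled with right singular vectors of the
class-centered residual. LDA initialization starts the sampler inside a
subject-separating subspace. A caveat found while validating: with few
segments per subject the *individual* discriminant directions are
tilted substantially by sampling noise in the within-class scatter (the
effect is scale-free and disappears only when the within-class degrees
of freedom far exceed $s$), so initialization quality is checked by the
between/within variance ratio of the projected data and by the
sampler's recovery of $\Theta$, not by subspace angles at the default
ridge.

Defaults follow the analysis settings: $K = 30$, 1000 iterations, 500
burn-in, posterior means over retained draws as point estimates.
Convergence is monitored by split-$\widehat{R}$ and rank-normalized
bulk/tail effective sample sizes on 200 randomly sampled entries of
$\Theta$ (flagging ESS < 100), computed by the package itself since no
installed package provides the bulk/tail variants.

# Features

Recordings are band-passed at 1–45 Hz with a zero-phase
frequency-domain filter (raised-cosine transitions of 0.5 Hz; any
linear-phase filter with equivalent stop-band behavior would do — the
frequency-domain form is exactly zero-phase and costs two FFTs per
channel instead of a ~1700-tap convolution). Six 60-s segments are cut:
N1a/N1b at the start and end of the N1 block, N2a/N2b adjacent early in
N2, N2c/N2d later, so that segment pairs span a range of temporal
separations. Welch PSDs use a 1024-sample Hamming window with 50%
overlap at 250 Hz (0.244 Hz resolution; overlap is the standard choice,
the analysis is insensitive to it). Thirteen bands tile 1–42.6 Hz with
widths growing by exactly 0.2 Hz from 2 Hz; band power is the trapezoid
integral of the PSD over the band (interpolating at band edges), and
relative power divides by the total over the 13 bands of the same
channel, so each channel's 13 values sum to exactly 1 and overall
amplitude scaling (cap fit, skull thickness) cancels. With 19 channels
this gives $s = 247$ features per segment. Feature matrices are
Z-scored per column; in cross-validation the test fold is always
transformed with the training fold's parameters.

# Fingerprinting

Observations are projected into the latent space as
$\mathbf{Y}\Gamma^{+}$ (right pseudo-inverse of the posterior-mean
$\Gamma$ — least-squares coordinates; the minimum-norm solution is used
with a warning if $\Gamma$ is rank-deficient). Identification compares
one segment per subject against another: entry $(i,j)$ of the paired
matrix is the L1 distance between subject $i$'s segment-a projection
and subject $j$'s segment-b projection (L1 rather than Euclidean for
its better contrast in higher dimensions). Subject $i$ is correctly
identified when the row minimum falls on the diagonal; ties break to
the lowest column index with a warning. The correlation baseline scores
the same pairs by Pearson correlation on all 247 features (row maximum
instead of minimum). Scoring is row-wise by default, with a symmetric
option averaging row- and column-wise rates.

Per-subject *differentiability* is the Z-score of the self pair against
that subject's distances to all others,

$$D_{\mathrm{self}}(i) = -\frac{d(a_i, b_i) - \mu_{d\setminus i}}
  {\sigma_{d\setminus i}},$$

negated for distances (not for similarities) so larger always means
more distinct; $\sigma_{d\setminus i}$ is the sample SD over the
$N - 1$ other distances. Cross-validation folds partition *subjects*:
the model is fitted on training subjects, held-out subjects are
projected through the trained $\Gamma$, and identification is scored
among held-out subjects only. `generalize()` scores segment pairs not
used in training through the same projection, and when a training set
mixes stages, the self pair for scoring is the two same-stage segments.

# Group statistics

* **Cluster-level permutation test**: per frequency bin, a one-way
  repeated-measures F across segment labels; bins above the
  $1-\alpha$ quantile ($\alpha = 0.01$) of $F(d_1, d_2)$ form
  contiguous clusters scored by summed F, against a null of maximal
  cluster mass under within-subject label permutations (default 1000;
  p-values use the $(\mathrm{count}+1)/(n+1)$ convention). The
  threshold df convention $d_2 = n_{\mathrm{subj}}$ is the default,
  with the conventional $(I-1)(J-1)$ error df available; the choice
  moves the cluster-forming threshold slightly, and the permutation
  null keeps the cluster-level error rate calibrated either way.
* **Mantel test**: Pearson correlation of vectorized off-diagonal upper
  triangles after symmetrizing paired matrices as $(M + M^\top)/2$;
  simultaneous row/column permutations of one matrix (999 by default);
  one-sided for positive association, matching the direction of every
  comparison the analysis makes.
* **Differentiability regression**: OLS of per-subject scores on the
  EMG noise covariate $|\log \mathrm{RMS}_{a} - \log \mathrm{RMS}_{b}|$
  (the two fingerprinting segments), sex, age, cap size, and
  noise-by-sex; N1-type analyses add age-by-sex. Factors are coded with
  female and small-cap reference levels; rank-deficient designs (e.g.,
  a single-sex cohort with the interaction) raise an error naming the
  aliased terms.
* **AUC-age regression**: cubic polynomial with HC3
  heteroskedasticity-robust standard errors (robust flavor unspecified
  upstream; HC3 is the conservative small-sample default), capturing
  the rise-then-fall of total spectral power across childhood.

# The synthetic cohort

`generate_cohort()` draws subject parameter sets; `simulate_recording()`
turns each into a 900-s 19-channel signal. What is emulated, and why:

* **Ages** from a gamma distribution (shape 1.15, scale 4.0, truncated
  to 0.1–19 y), giving mean ≈ 4.6 y, SD ≈ 4.3 y and a majority of
  subjects under 5 — the right-skewed make-up of clinical pediatric
  cohorts.
* **Aperiodic background** $10^{c}/f^{\chi}$ with $\chi \in [0.8, 2]$,
  realized by exact frequency-domain shaping of white noise (an AR
  approximation would be harder to verify spectrally). The offset $c$
  follows an inverted U in age (gamma-shaped age term peaking at 2 y):
  total power rises over the first years and declines thereafter.
* **Sleep spindles**: every subject has a 12–15 Hz peak whose amplitude
  grows with age (saturating over ~3 y) and whose power gain is
  strictly larger in N2 than N1 — the stage signature the cluster test
  should find. Subjects older than ~1 y usually add a slower
  theta/alpha peak whose frequency matures with age.
* **Idiosyncrasy**: stable per-subject channel gains, offset and
  spindle-amplitude deviations — the signal that makes individuals
  identifiable. `cohort_config_high_idiosyncrasy()` strengthens these
  (channel-gain SD 0.3, offset SD 0.3, spindle-amplitude SD 0.5) and
  weakens drift; it is the demo regime in which cross-validated
  identification should approach 1.
* **Non-stationarity**: a slow multiplicative random-walk gain across
  epochs, so far-apart segments resemble each other less than adjacent
  ones.
* **EMG artifact**: broadband 15–125 Hz noise with per-segment
  log-normal amplitude whose spread shrinks with age; per-segment RMS
  is recorded into the cohort table for the noise covariate. An
  optional wake-contamination flag replaces random N1 epochs with
  wake-like content (spindle silenced, EMG doubled) for robustness
  experiments; it is off by default so stage labels are exact.

What is *not* emulated: cardiac/ocular artifacts (real-data users
pre-clean with ICA upstream), volume conduction and genuine spatial
correlation structure between channels (channels are independent given
the subject's parameters), mislabeled sleep stages, and any
between-session variability. Passing tests on this generator therefore
demonstrate correctness of the algorithms and calibration of the
statistics under the stated generative assumptions — not clinical
performance on real EEG; none of the clinical cohort's headline numbers
are reproducible here, which is why the package's acceptance checks are
property-based (recovery, calibration, contracts) rather than
value-matching.

`simulate_from_brrr()` bypasses the signal level entirely and draws
directly from the model equation with known $\Psi, \Gamma, \Omega,
\Sigma$, for sampler recovery tests; its default noise scales (latent
SD 0.1, residual SD 0.5) match the model's low-latent-noise assumption,
and recovery is also verified at latent SD 0.3.

# Numerical choices and degenerate inputs

* Half-open bands $[l, h)$ resolve shared edges; a PSD that is zero
  over 1–42.6 Hz in any channel is a degenerate-channel error rather
  than silent NaNs.
* Zero-variance feature columns in Z-scoring get an SD floor of
  $10^{-6}$ (from variance $10^{-12}$) with a warning.
* The repeated-measures F uses a scale-aware floor on the error mean
  square so numerically identical segments give F = 0, not 0/0.
* Nearest-neighbor ties break to the lowest index, logged; constant
  distance rows make differentiability NA with a warning rather than
  ±Inf.
* The elbow rule picks the smallest grid K whose success-rate gain over
  the previous point is below 1 percentage point (the notion of
  "diminishing returns" made explicit); with a single-point grid it
  returns that K.
* All Monte Carlo procedures (sampler, permutations, folds,
  subsampling) take explicit integer seeds and are bit-reproducible.

# Problem sizes

The test-suite and acceptance scenarios run at desk scale, chosen as
the smallest sizes at which each property is statistically decisive:
sampler recovery and convergence on 40 subjects × 2 segments with
$s = 60$, $k = 4$ at the full 1000 iterations; the signal-level
pipeline on cohorts of 12–30 subjects; cluster-test calibration on 200
replicates of 30 subjects with 500 permutations; chance-level
calibration on 2000 simulated distance matrices of 20 subjects. The
model itself has no scale-dependent logic, so these sizes exercise the
same code paths as cohort-scale runs.

# Known limitations

* A single MCMC chain is used (diagnostics split it); there is no
  multi-chain or variational alternative.
* $\Psi$ and $\Gamma$ are identified only up to rotation/scale;
  everything user-facing depends on $\Theta = \Psi\Gamma$, the fitted
  subspace, or distances, which are invariant.
* The latent-noise variance is a fixed prior scale, not learned; if the
  true latent noise is far from the prior scale the model compensates
  through $\Sigma$ and recovery degrades gracefully (tested at 3× the
  prior scale).
* The correlation baseline uses all features and no tuning, exactly as
  commonly practiced — it is a reference point, not an optimized
  competitor.
* EDF input is not supported in this environment; recordings live in
  memory and tables serialize to CSV/JSON.
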