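---
title: "Methods: simulation, features, balancing and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, features, balancing and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Seizure epochs are rare: in clinical EEG archives only a few percent of
recorded segments contain ictal activity. A classifier trained on such data
can reach high accuracy while missing most seizures, because the loss is
dominated by the background class. `eegaug` packages the full workflow for
studying remedies to this imbalance — minority oversampling (SMOTE, ADASYN),
cost-sensitive class weighting, and generative augmentation with GANs,
evaluated under patient-grouped cross-validation so that no patient's data
ever straddles a train/test boundary.

Because clinical corpora are access-controlled, the package ships a
synthetic-data module that emulates their shape. Every experiment below is
reproducible from a single integer seed.

# The EEG simulator

`simulate_eeg_dataset()` produces patient-structured epochs of
channels-by-samples matrices.

**Background.** Each channel is a sum of five band-limited oscillators
(delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz) with
amplitudes 2.0, 1.2, 1.0, 0.5, 0.25 — a pink-ish spectrum — plus white
noise (SD 0.5). Frequency and phase are redrawn per epoch; each band's
strength is additionally scaled by a per-epoch Uniform(0.4, 1.6) factor,
emulating the several-fold band-power fluctuation of resting EEG across
vigilance states. Without that variability every epoch has a nearly
identical spectral profile and the detection task collapses to a trivial
threshold.

**Patients.** Each patient carries a log-normal amplitude factor
(`patient_effect_sd`, default 0.2 on the log scale), constant across all
of that patient's epochs. This is what makes grouped cross-validation
meaningful: epochs of one patient are correlated.

**Seizures.** A labeled epoch adds a 3 Hz rhythmic burst with 2nd and 3rd
harmonics (relative amplitudes 1 : 0.5 : 0.3), scaled to 3 times the
epoch's background SD, on `ceiling(n_channels / 3)` randomly chosen
channels. Label counts are realized exactly — `round(fraction * n)` (round
half up) positive epochs placed by sampling without replacement — so tests
are deterministic at a fixed seed rather than Bernoulli-noisy.

**Epoch duration** defaults to 4 s: the 0.5 Hz lower delta edge then fits
two full cycles per epoch, the minimum for a usable band-power estimate.
The corpus this emulates does not fix an epoch length, so it remains a
parameter.

At this signal-to-background ratio the seizure signature is strongly
discriminative: Random Forests reach near-perfect minority recall at desk
scale. The augmentation comparisons on extracted EEG features are therefore
ceiling-limited; the feature-space simulator (below) provides the harder,
controllable regime where augmentation gains are visible.

**What the simulator does not model:** artifacts and eye blinks (the
archives this emulates were manually cleaned), inter-channel correlation
structure, montage re-referencing, seizure evolution across epochs, and
morphology variation between patients. Passing tests on simulated data
show the pipeline's mechanics and ordering properties, not clinical
performance.

# The feature-space simulator

`simulate_feature_dataset()` draws a labeled feature table directly from
known per-class Gaussians (optionally mixtures) with exact class counts and
round-robin patient assignment. It is the ground truth for
augmentation-recovery experiments: when a GAN is trained on minority rows
drawn from a known distribution, its samples can be scored against that
distribution exactly.

# The 44-feature descriptor set

`extract_feature_vector()` computes 44 features per channel and
concatenates them channel-major (all features of channel 1, then channel
2, …), giving 836 values for a 19-channel montage. Families and choices:

* **Band powers (15).** Welch PSD with 1 s Hann segments, 50% overlap.
  Per band: average (mean in-band density), absolute (integrated power),
  relative (absolute / total over the five bands; sums to 1).
* **Moments (3).** Unbiased variance; population-moment skewness and
  excess kurtosis.
* **EMD (6).** In-house sifting (cubic-spline envelopes through interior
  extrema with endpoints appended, stop when the normalized squared
  envelope-mean drops below 0.09 or after 50 passes, at most 8 IMFs).
  Energy, normalized spectral entropy, mean, SD, second central moment and
  skewness of the **first** IMF — the highest-frequency mode, where
  rhythmic discharges concentrate.
* **Entropies (5).** Sample entropy (m = 2, r = 0.2 SD), vectorized over
  the template-distance matrix; permutation entropy at embedding orders
  3–6 (the "4 levels"), delay 1, each normalized by log(order!) to [0, 1].
* **Hjorth (3).** Mobility, activity (= variance), complexity, from first
  differences.
* **Spectral entropy (1).** Shannon entropy of the normalized PSD over
  0.5–45 Hz, divided by log(#bins).
* **Wavelets (8).** db4, periodized with zero-padding to a multiple of
  2^5 so the transform is orthonormal and Parseval holds exactly.
  Shannon entropy of the 5-level DWT coefficient-energy distribution;
  log-energy and Shannon entropies of the 8 depth-3 wavelet-packet node
  energies; percentage of total energy per detail level (the remainder
  sits in the deepest approximation, so the five percentages sum to
  ≤ 100).
* **SDI + energies (3).** The successive decomposition index is computed
  by repeated pairwise Haar-style averaging of |x| (each pass halves the
  length, scaling by 1/√2) down to one coefficient, reported as log1p of
  it — a cheap amplitude summary that rises sharply during rhythmic
  high-amplitude activity. Mean energy and cumulative energy complete the
  set (cumulative = n × mean, kept for descriptor-set compatibility).

**Degenerate-input rule.** Any feature undefined on a constant or zero
channel (band powers, entropies, wavelet features, EMD statistics) returns
0 with a logged warning instead of erroring, so a flat channel never kills
a pipeline run.

Feature names are frozen (`chXX_<family>_<name>`) and published through
`feature_dictionary()`.

# Balancing strategies

All neighbor searches run on standardized features (Euclidean metric,
deterministic index tie-breaks); interpolation happens in the original
feature space.

* **SMOTE** (`smote_oversample()`): each synthetic row is
  `x_i + λ (x_j − x_i)` with λ ~ Uniform(0, 1), `x_j` one of the k = 5
  nearest minority neighbors of a uniformly drawn minority row. The random
  stream order (base row, neighbor slot, λ) is fixed and documented, so an
  external reference fed the same stream reproduces the output exactly —
  that is how the tests verify it.
* **ADASYN** (`adasyn_oversample()`): the density ratio `r_i = Δ_i / K`
  counts majority samples among the K = 5 nearest neighbors *in the full
  table*; normalized ratios allocate `G` synthetic samples by
  largest-remainder rounding (`Σ g_i = G` exactly); generation then
  interpolates toward random minority neighbors. If no minority point has
  a majority neighbor the allocation falls back to uniform with a warning.
* **Class weighting** (`compute_class_weights()`):
  `w_c = n_total / (2 n_c)`, the mean-normalized inverse frequency; enters
  the classifiers' loss, creates no rows.
* **GANs** (`train_gan()`): see below.

`balance_dataset()` applies one strategy up to a target minority:majority
ratio (default 1:1), flags every appended row `is_synthetic = TRUE`, and
never modifies an original row.

# GAN variants

All four variants share the same tabular backbone: a generator MLP (noise
→ tanh hidden layers → linear output) and a critic/discriminator MLP,
trained with Adam on minibatches, with features standardized internally
(z-scores) and de-standardized on generation so that scale disparities
between feature families (energies vs entropies) do not dominate the
critic.

* **vanilla** — original adversarial game, sigmoid discriminator, binary
  cross-entropy, non-saturating generator loss.
* **cgan** — the label is appended to both generator input and
  discriminator input; training uses both classes, generation conditions
  on the minority label.
* **cramer** — implemented as the energy-distance surrogate of the Cramer
  objective: the generator directly minimizes the sample energy distance
  between its batch and a real batch (no critic network). This is a
  documented approximation of the original critic-based formulation.
* **wgan_gp** — Wasserstein critic loss plus gradient penalty
  `λ (‖∇_x̂ f(x̂)‖₂ − 1)²` at interpolates `x̂ = ε x_real + (1−ε) x_fake`,
  λ = 10, five critic updates per generator update. The penalty's
  parameter gradients are exact: the input-gradient computation is
  differentiated analytically (forward tangent + adjoint pass through the
  tanh network), verified against finite differences in the tests.

**Optimizer defaults.** Vanilla/CGAN/Cramer use Adam(0.001, β₁ = 0.9,
β₂ = 0.999), matching the classifier setup. WGAN-GP defaults to the
original Wasserstein-GP prescription Adam(1e-4, β₁ = 0, β₂ = 0.9): with
the momentum-heavy setting the critic trains stably for roughly a hundred
epochs and then diverges (generated-sample energy distance to held-out
data worsens several-fold), which the low-momentum setting eliminates.
Both are overridable per run.

Training aborts with a diagnostic on a non-finite loss. The per-epoch loss
trace is stored on the model; with `track_every > 0` and tracking data the
model also records an energy-distance trace.

# Fidelity diagnostics

* `qq_compare()` pairs empirical quantiles (linear interpolation of order
  statistics) at probabilities `(i − 0.5)/100` and reports the maximum
  absolute deviation from the diagonal; a location shift of c moves the
  deviation to exactly |c|.
* `distribution_distance()` is the multivariate energy distance computed
  with full-pair (V-statistic) means, so it is symmetric, non-negative and
  exactly zero on identical samples.
* `project_2d()` overlays real and synthetic rows in 2-D via truncated
  SVD, RBF kernel PCA, FastICA (symmetric decorrelation, logcosh) or exact
  t-SNE (perplexity 30, O(n²) — diagnostic sample sizes only). Projections
  are diagnostics, not gates: no pass/fail threshold is imposed on them.

# Classifiers and evaluation

* **Random Forest** — 500 trees by default, seeded; the benchmark model.
  Class weights enter as `classwt`.
* **LSTM** — two layers of 10 units, dense sigmoid head, binary
  cross-entropy (optionally class-weighted), Adam(0.001, 0.9, 0.999),
  up to 100 epochs with early stopping after 20 epochs without
  validation-loss improvement. The validation slice is the last 10% of
  training-fold patients (grouped, synthetic rows excluded), since nothing
  else in a fold is safely held-outable. The 44·C feature vector is
  reshaped channel-major into C timesteps × 44 features (inferred from the
  `chXX_` name prefixes; a single-timestep mode covers generic tables).
  Direction is a switch: unidirectional by default — the architecture
  description governs over a conflicting summary elsewhere — with a
  bidirectional option. Gates are implemented from first principles and
  the full backpropagation-through-time is verified against finite
  differences in the tests.
* **Decision threshold** fixed at 0.5; no tuning.

`group_kfold_splits()` assigns whole patients to 10 folds greedily
(largest patient first into the smallest fold), so folds are
patient-disjoint and test folds partition the rows. `run_experiment()`
fits augmentation **inside** each training fold (the GAN sees only
training-fold minority rows), trains, evaluates on the untouched test
fold, and averages the metric suite (loss, accuracy, recall, specificity,
precision, F1, confusion counts) across folds. Reports serialize to JSON
with config hash and seeds for provenance.

# Numerical choices and edge cases

* Quantile type 7 (R default) everywhere quantiles appear.
* `largest_remainder()` integerizes allocation quotas with ties broken by
  index.
* kNN distance ties break by row index; all stochastic draws flow from one
  integer seed through a single RNG, and cross-validation derives per-fold
  child seeds deterministically.
* Metrics with zero denominators (e.g. precision with no positive
  predictions) report 0 with a warning rather than NaN.
* Sample entropy returns 0 (with the degenerate rule) when no template
  pair matches at m + 1 on a constant signal, and `Inf` is mapped to 0 in
  the feature vector.

# Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is stable: 1,000
simulated epochs for the finiteness sweep; 500 training draws and 1,000
generated samples for the 2-D WGAN-GP recovery check; 300 mixture draws
× 10 seeds for the energy-distance-decrease check; and a 20-patient,
600-epoch, 4-channel dataset for the grouped 10-fold end-to-end
comparison (4 seeds, Random Forest). The analysis scripts under
`analysis/` run the same pipeline on the full 19-channel montage.

# Known limitations

* The simulator's fixed-amplitude seizure signature makes the raw-EEG
  detection task nearly separable at desk scale, so end-to-end
  augmentation gains appear as ties at ceiling; the informative
  augmentation comparisons are the feature-space experiments.
* The Cramer variant is a surrogate, not the original critic-based
  objective.
* EMD sifting uses a simple envelope/stop rule; mode mixing on broadband
  signals is not addressed.
* t-SNE and kernel PCA are exact/O(n²) and meant for hundreds of rows.
* No hyperparameter search anywhere: defaults are fixed a priori and
  exposed as configuration.
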