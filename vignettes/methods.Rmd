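---
title: "Methods: time-frequency EEG features for dementia discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-frequency EEG features for dementia discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`adeeg` implements a classical (non-deep) pipeline for discriminating
Alzheimer's disease (AD), mild cognitive impairment (MCI) and healthy
controls from resting-state, eyes-closed scalp EEG in the 19-channel 10-20
montage. The premise is the well-documented *spectral slowing* of the AD
EEG — power shifts from the alpha/beta bands toward delta/theta — together
with a loss of signal complexity (lower entropies, lower fractal
dimensions). The pipeline turns each recording into one fixed-length
feature vector and lets a roster of standard classifiers separate the
groups pairwise:

1. **Preprocess** every recording: resample to a common 256 Hz, divide each
   channel by its RMS, remove the channel mean, band-pass 1–40 Hz.
2. **Feature bank**: slide a 1-second non-overlapping window over every
   channel and compute 43 time-frequency metrics per window.
3. **Temporal compression**: reduce each (channel, feature) time series to
   10 summary statistics.
4. **Pairwise datasets**: stack the two groups of a contrast into a
   subjects × (channels · 43 · 10) matrix — 14 × 8170 for the balanced
   7 + 7, 19-channel design — and min-max normalize each column to [0, 1].
5. **Classify** with 15 classifiers under stratified 7-fold
   cross-validation, pooling the test predictions of all folds into one
   confusion matrix per classifier.

## Preprocessing conventions

- **Resampling** uses the Fourier method: the DFT is truncated or
  zero-padded at the new Nyquist frequency and inverted at exactly
  `round(n · target_fs / fs)` samples. This is anti-aliased by construction
  and length-exact. Fidelity is audited as the Pearson correlation of the
  1–40 Hz magnitude spectra of the original and resampled signal
  (edge-trimmed by 0.5 s); values stay above 0.99 on band-limited signals.
- **RMS normalization** maps every channel to unit root-mean-square, which
  removes inter-subject and inter-device amplitude scale. Mean removal then
  centers each channel at exactly zero.
- **Filtering** is a 5th-order Butterworth band-pass (1–40 Hz) applied
  forward and backward (`filtfilt`), i.e. zero-phase with a squared
  magnitude response.

## The 43-metric feature bank

Windows are `round(window_seconds · fs)` samples (256 at the defaults); all
metrics are computed per window, per channel, in a fixed documented order
(`feature_names()`).

**Entropy (6).** Shannon entropy of the 16-bin amplitude histogram
(natural log, unnormalized); permutation entropy (order 3, delay 1, ties
broken by temporal position, normalized by `log(3!)`); spectral entropy of
the one-sided periodogram (normalized by the log bin count); SVD entropy of
the order-3 delay embedding (normalized by `log(3)`); approximate entropy
(`m = 2`, tolerance `0.2 ·` population SD, Chebyshev distance, self-matches
included) and sample entropy (`−ln(A/B)`, self-matches excluded, both
template lengths counted over the common `N − m` templates). Degenerate
(constant) windows report 0 with a diagnostic condition.

**Basic statistics (12).** Min, max, mean, RMS, population variance and SD,
crest factor (`max|x| / RMS`), population skewness, non-excess kurtosis,
and the 25/50/75th percentiles (type-7 linear interpolation). Crest factor,
skewness and kurtosis of a zero-variance window are defined as 0.

**Power spectral density (11).** The one-sided periodogram
`|X(f)|² / (fs·N)` (interior bins doubled) restricted to 1–40 Hz: total
power, PSD peak and peak-to-peak, the five band powers (δ 1–4, θ 4–8,
α 8–13, β 13–30, γ 30–40 Hz; half-open `[lo, hi)` except γ, which closes at
40 Hz so that the bands partition the total exactly), and the slowing
ratios `r1 = δ/(α+β)`, `r2 = θ/(α+β)`, `r3 = (δ+θ)/(α+β)`.

**Frequency domain (7).** Treating the spectral power on the 1–40 Hz DFT
grid as a weight distribution: maximum frequency with non-negligible power
(above `1e-6` of the peak), total spectral weight, power-weighted mean
frequency, median frequency (first cumulative-half crossing), peak
frequency, and power-weighted spectral skewness and kurtosis.

**Fractal dimension and complexity (7).** Zero-crossing count (strict sign
changes, zeros skipped); Katz fractal dimension; Higuchi fractal dimension
(`kmax = 10`); the DFA scaling exponent (cumulative-sum profile,
non-overlapping linearly detrended segments, 10 log-spaced scales from 4 to
N/4); Petrosian fractal dimension; Hjorth mobility and complexity. First
differences are taken in discrete sample units (not scaled by `fs`), which
is the common convention and is rate-free once all recordings share 256 Hz.

## Temporal compression and dataset assembly

Each of the 43 feature time series of each channel is summarized by 10
statistics — mean, median, min, max, population SD and variance, and the
25/50/75/95th percentiles. The median and the 50th percentile coincide
numerically; both are emitted to honor the 10-fold factorization of the
feature space, giving `19 × 43 × 10 = 8170` columns. Columns are labeled
`"channel|feature|statistic"`.

Min-max normalization uses the extrema over the *whole* pairwise matrix,
i.e. over training and test subjects together. This mirrors the original
study design and is deliberately kept as the default; it leaks fold
statistics, so a leak-free alternative (extrema from the training fold
only) is available via `run_cv(normalize_within_folds = TRUE)`.

## Classifier roster

The 15 classifiers and their frozen settings (`classifier_roster()`):

| name | implementation |
|---|---|
| `adaboost` | discrete AdaBoost (SAMME), 50 weighted depth-1 CART stumps (compiled) |
| `bagging` | 10 bootstrapped unpruned CART trees (compiled) |
| `decision_tree` | single unpruned CART tree (compiled gini, exhaustive splits) |
| `extra_trees` | `ranger`, extratrees splitting, 100 trees, no bootstrap |
| `gaussian_nb` | `e1071::naiveBayes`, zero-variance guard 1e-9 |
| `gaussian_process` | `kernlab::gausspr`, RBF kernel, automatic width |
| `gradient_boosting` | `xgboost`, depth 3, eta 0.1, 100 rounds |
| `knn` | `class::knn`, k = 5 |
| `lda` | `MASS::lda` after projection onto the training SVD subspace |
| `logistic_regression` | `glmnet` ridge, fixed penalty 1/n |
| `logistic_regression_cv` | `glmnet::cv.glmnet` ridge, 3-fold inner CV |
| `mlp` | single hidden layer, 100 ReLU units, full-batch Adam, L2 1e-4 |
| `random_forest` | `randomForest`, 500 trees |
| `sgd` | linear hinge loss, Pegasos-style SGD, L2 1e-4 |
| `svm` | `e1071::svm`, RBF, `gamma = 1/p`, cost 1, no rescaling |

Two substitutions are worth noting. Formula-based tree engines cannot
handle 8170-column design matrices efficiently, so the tree family runs on
a small compiled CART (gini impurity, exhaustive midpoint-threshold search,
sample weights). Quasi-Newton neural-network trainers need memory quadratic
in the weight count — prohibitive at `p = 8170` — so the MLP is trained
with full-batch Adam, matching the common default for this model class.

With 7 + 7 subjects and 7 stratified folds, every test fold holds exactly
one subject per class. Metrics are **pooled**: the 14 held-out predictions
form one confusion matrix, from which accuracy, recall (sensitivity),
precision, F1 and specificity are computed; undefined ratios are reported
as 0. AUC is the rank-based area under the ROC of the pooled continuous
scores (class 1, the more-affected group, is positive). On 14 subjects the
accuracy granularity is 1/14, so values such as 13/14 ≈ 92.86% are the
representable steps below 100%.

## The synthetic cohort generator

Clinical EEG cannot be shipped with the package, so a generator produces
cohorts with the group-dependent spectral structure the pipeline is meant
to detect. Each channel is an independent sum of five band-limited
Gaussian-noise components (5th-order Butterworth-filtered white noise,
rescaled to an exact target band power) plus a `1/f` pink background:

- `control`: band weights (δ, θ, α, β, γ) = (0.5, 0.7, 1.5, 1.0, 0.3),
  sampled at 200 Hz — a posterior-alpha-dominant, faster spectrum; the
  lower rate also exercises the resampling stage.
- `ad`: (1.5, 1.4, 0.6, 0.4, 0.2) at 256 Hz — slowed, delta/theta-dominant.
- `mci`: the midpoint of the two, at 256 Hz.

The background power is the total structured power divided by `snr = 5`,
with pink exponent 1 — moderate broadband noise so the group structure is
present but not trivially clean. These defaults model the study conditions;
they are fixed and are not adjusted per analysis. Everything is
deterministic given one integer seed, fanned out per subject and channel.

## Problem sizes and runtime

A 60-s, 19-channel recording yields 60 windows per channel, 19 × 60 × 43
feature evaluations, and compresses to one 8170-vector in roughly 5 s
(entropy and Higuchi kernels are compiled). The full balanced cohort —
generation, preprocessing, features, compression, assembly — takes about
1–2 minutes; a 15-classifier cross-validated report on one pair adds about
1.5–2 minutes, dominated by the MLP and the naive Bayes predictions.

## Limitations

- Synthetic channels are independent; real EEG has strong spatial
  correlation, volume conduction and artifacts, none of which are modeled.
- The default whole-matrix normalization leaks across folds (kept for
  fidelity to the original design; see above for the leak-free option).
- Hyperparameters are frozen; no tuning or nested cross-validation.
- With 14 subjects per contrast, metric granularity is coarse (1/14), and
  AUC estimates from 7 positives × 7 negatives are noisy.
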