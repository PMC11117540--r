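---
title: "Methods: graphical FrFT analysis of EEG epochs"
author: "frfteeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graphical FrFT analysis of EEG epochs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frfteeg)
```

# Overview

`frfteeg` classifies fixed-length EEG epochs as *normal* or *alcoholic*
through a chain of five stages: artifact screening and (for multichannel
input) multiscale PCA denoising, a stage-filtered fast fractional
Fourier transform (FrFT) that maps an epoch to an ordered complex
scatter, 34 geometric features of that scatter, an ensemble feature
selector, and small neural-network classifiers under stratified
cross-validation. This vignette records the model assumptions, the
parameters that matter, and the design and numerical choices behind the
implementation.

# Preprocessing

Recordings are assumed to be voltages in microvolts sampled at a common
rate (`fs`, default 256 Hz). Epochs are consecutive, non-overlapping,
half-open windows of `epochLen` samples (default 2048, i.e. 8 s at
256 Hz); a trailing remainder shorter than one window is dropped, so a
32 s recording yields exactly four epochs. An epoch is flagged as an
artifact when any sample exceeds `artifactThresholdUv` (default
73.3 uV) in absolute value — the conventional screening level for blink
and movement interference — and flagged epochs are excluded wholesale.
Per-sample clipping or interpolation is deliberately not offered: an
epoch that contains a movement artifact is not trustworthy.

## MSPCA denoising

The observed signal is modelled additively, `Q = Q_EEG + Q_N`, with the
neural component correlated across channels and the artifact/noise
component much less so. Denoising therefore works on a channels x time
matrix:

1. 5-level discrete wavelet transform (Symlet-4) of every channel;
2. PCA across channels on each subband coefficient matrix, keeping the
   components whose eigenvalue strictly exceeds the mean eigenvalue
   (Kaiser-style rule) and back-projecting;
3. inverse wavelet transform;
4. the same PCA retention once more on the reconstructed time-domain
   matrix.

Design notes:

* **PCA across channels, not epochs.** The method's premise is
  cross-channel correlation of simultaneously recorded signals;
  independently generated trials have no such correlation, so the
  pipeline skips MSPCA for the synthetic epoch stream and applies it
  only to multichannel recordings.
* **Retention rule.** "Eigenvalue strictly greater than the mean" can
  retain nothing when all eigenvalues are equal; the first component is
  then kept so the output is never empty.
* **Centering.** Channels are mean-centered per band; the means are
  added back after projection, so the operation is non-expansive on the
  centered energy.
* **Wavelet implementation.** No DWT was available among the package's
  allowed dependencies, so the transform is implemented here from the
  standard published Symlet-4 filter coefficients, with whole-sample
  symmetric boundary extension and the usual `floor((n + F - 1)/2)`
  per-level length rule. Perfect reconstruction is property-tested to
  below 1e-8 maximum absolute error (observed: ~1e-12).

# The fast FrFT graphical transform

For an epoch `x(n)` of power-of-two length `N` and order `alpha`
(default 0.5), the transform runs `log2(N)` stages. Stage `k`
multiplies the signal by the chirp filter

```
f_k(m) = ((m + 1) / 2) * exp(i * pi * K * (m - N/2)^2 / 2^k),
K = exp(-i * pi * alpha / 2),  m = 0..N-1,
```

takes an N-point FFT, scales by `K^(2^(k-1))`, and inverse-FFTs back.
After the stage loop the fractional coefficients are a chirp-modulated
DFT,

```
c_k = (1/N) * sum_n y(n) * exp(-i*pi*alpha*(n - N/2)^2 / N)
                        * exp(-2*pi*i*n*k / N),
```

computed with a single FFT. The ordered pairs `(Re c_k, Im c_k)`,
`k = 0..N-1` (no fftshift), form the 2D scatter.

Design and numerical notes:

* **Stage length.** The stage description's per-stage FFT length
  `2^k` conflicts with filtering a length-N signal; the implementation
  uses full-length N-point FFT/IFFT at every stage, with the stage
  index entering only through `f_k` and the `K^(2^(k-1))` scale. The
  O(N^2) direct-evaluation oracle in the test suite implements exactly
  the same convention with literal DFT sums, pinning the semantics.
* **Chirp conventions.** Because `K` is complex, the exponent of `f_k`
  has a real part that grows like
  `pi * sin(pi*alpha/2) * (m - N/2)^2 / 2^k`; in double precision this
  overflows for `N > 32` at `alpha = 0.5`. The package therefore
  supports two kernels: `chirp = "complex"` (the definition above,
  exact for small N, used in all oracle-equivalence tests at N = 16)
  and `chirp = "real"`, which substitutes the real order `alpha` for
  `K` inside the chirp exponent, giving a bounded pure-phase filter
  valid at any length. The default `"auto"` selects `"complex"`
  whenever it cannot overflow and `"real"` otherwise — production
  epochs (N = 2048) use the pure-phase kernel.
* **Linearity.** Every step is linear in the signal; linearity and the
  `alpha = 0` kernel degeneracy (the coefficient chirp becomes 1) are
  tested directly.

# The 34 graphical features

Features are functions of the ordered scatter `P_i`, `i = 0..N-1`,
with the "coordinate center" fixed at the origin (the transform centers
the cloud by construction; a centroid-referenced variant would change
F10, F12 and the CTMs only by a shift). The canonical order is
`graphicalFeatureNames()`: SCCA, SCTA, SHCA, SDHC, SAHC, SSVL, SH45,
SH135, AOCT, SDTC, SATP, TACR, SCRA, TDSD, ELPA, CTM1..CTM19.

Interpretations fixed by this package (each pinned by an independent
brute-force oracle in the tests):

* **F1 (SCCA)** sums circle areas with the consecutive-point distance
  as *diameter*; **F2 (SCTA)** sums consecutive-triple triangle areas.
* **F3–F5 ("Heron's circulars")** are the circumcircles of consecutive
  triples, radius `R = abc / (4A)`: summed areas (F3), summed distances
  between successive circumcenters (F4), summed interior angles of
  circumcenter triples (F5). Triples with area below `1e-12 x scale^2`
  are skipped from all three sums — a near-collinear triple has an
  astronomically large, numerically meaningless circumcircle.
  Circumcenters are computed in vertex-relative coordinates to avoid
  cancellation of large squared magnitudes.
* **F7/F8** are summed point distances to the 45- and 135-degree lines
  (`|x - y|/sqrt(2)`, `|x + y|/sqrt(2)`); **F13 (SCRA)** multiplies the
  two distances per point.
* **F9 (AOCT)** is the area of the intersection of the eight support
  half-planes at 45-degree spaced directions; with sorted tangent
  directions, consecutive support-line intersections are the polygon
  vertices and the shoelace formula gives the area.
* **F11 (SATP)** sums interior angles at the middle point of
  consecutive triples, in `[0, pi]`; zero-length arms are skipped.
  F5 uses the same rule on the circumcenter sequence, keeping the two
  angle features consistent.
* **F14 (TDSD)** reduces the two Poincare descriptors to one number:
  SD1 + SD2, the sample standard deviations (1/(n-1)) of the
  projections perpendicular to and along the identity line.
* **F15 (ELPA)** is `pi * sqrt(lambda1 * lambda2)` of the 2x2 sample
  covariance.
* **F16–F34 (CTMs)** use radii `(k/20) * r_max`, `k = 1..19` — a
  concrete reading of "different percentiles" that yields 19 monotone
  values in [0, 1]. An all-origin cloud defines every CTM as 1.
* Single-point and degenerate clouds give 0 for all sums and are never
  errors; an empty cloud is an error.

Scale equivariance (lengths scale with `s`, areas with `s^2`, angles
and fractions not at all), rotation invariance of the origin-referenced
features, and the order-dependence audit are part of the test suite.

# Ensemble feature selection

Five univariate scores per feature: information gain over 10
equal-width bins (entropies in bits), a full ReliefF (min-max scaled
features, `k = 10` nearest hits/misses in the complete feature space),
population variance (1/m), an NCA-style leave-one-out soft-neighbour
score with exponential kernel and bandwidth equal to the mean absolute
pairwise difference, and the absolute point-biserial correlation (the
printed CFS expression reduces to this because its self-correlation
terms are identically 1). Scores are min-max normalized per scorer
(constant rows become zeros), combined as a weighted mean (equal
weights by default), and the top K = 16 features are kept, ties broken
towards the lower index. A `mode = "cfs"` variant selects on the
correlation score alone, since the reference workflow is described
both ways; both are exposed rather than adjudicated.

One property worth recording: with balanced classes, the NCA score of a
perfectly separated feature does *not* approach 1 — the bandwidth
estimate grows with the class separation, so the score saturates near
`49 / (49 + 50 * exp(-1/0.505)) ~ 0.877` at m = 100. The constant
feature limit `(m/2 - 1)/(m - 1)` and this saturation value are both
asserted in the tests.

# Classifiers

Six architectures, trained on z-scored features (statistics from the
training split only, stored in the model):

| kind | topology | activation | learning rate | epochs |
|------|----------|------------|---------------|--------|
| slnn | 1 x 50   | ReLU       | 0.01          | 100    |
| mlnn | 100 + 100| tanh       | 0.05          | 200    |
| ffnn | 1 x 200  | sigmoid    | 0.1           | 150    |
| cfnn | 1 x 100 + input-to-output skip | ReLU | 0.01 | 100 |
| rnn  | Elman, 50 units | tanh | 0.01         | 200    |
| grnn | kernel regression, sigma = 0.5 | Gaussian | — | — |

Unstated training details are fixed as: full-batch gradient descent on
cross-entropy, weights initialized uniformly in [-0.5, 0.5] from a
seeded generator, sigmoid output thresholded at 0.5. The two-layer
depth of `mlnn` and the recurrent network's presentation of the feature
vector as a length-gamma sequence (one feature per time step, final
hidden state to a sigmoid readout) are interpretations of architecture
names given without wiring diagrams. The GRNN's "radius" parameter has
no role in standard kernel regression; it is read as a
prediction-confidence floor (kernel mass below `radius * m * eps` falls
back to the training majority class) and isolated behind the
configuration so it can be ignored.

# Evaluation

Folds are stratified: each class is shuffled with the seeded generator
and dealt round-robin, so 240 balanced samples give 10 folds of 24
(12 + 12) with 216 training samples each. Stratification is what makes
the 216/24 arithmetic hold per class; plain randomization would only
approximate it. Metrics per fold come from the confusion counts with
*alcoholic* as the positive class; sensitivity, specificity, precision,
accuracy and F1 are reported as percentages (displayed to 1 decimal),
Cohen's kappa on its natural scale. A zero denominator yields 0 with a
warning rather than NaN.

Feature selection placement is a genuine design fork: selecting once on
all data before cross-validation (as the reference experimental order
implies) leaks test information into the selector, while selecting
inside each training fold does not. Both modes exist
(`selection = "global"` / `"fold"`); the pipeline defaults to
`"fold"`. The Kruskal-Wallis screen (rank H statistic with tie
correction, chi-square p-value) is provided for per-feature analysis
and reporting, not as part of the selection path.

# The synthetic generator

Each trial is `sum_b A(class, b) * sin(2 pi f_b t + phi_b)` over four
band centers (delta 2, theta 6, alpha 10, beta 20 Hz) with per-trial
uniform phases, plus AR(1) noise (coefficient 0.85, innovation SD 3 uV)
— the simplest stationary colored-noise background — and optional
single-sample +/-200 uV spikes for artifact-rule testing. Defaults:
120 trials per class, 2048 samples at 256 Hz. The normal class uses
amplitudes (15, 8, 10, 4) uV; the alcoholic class defaults to exactly
half, making its scatter more concentrated towards the origin. The
amplitude levels keep a clean trial's peak below the 73.3 uV screening
threshold, so artifact exclusion removes nothing unless spikes are
injected. The published description of which class has the wider
scatter is internally inconsistent (figure caption versus discussion);
the generator therefore exposes the contrast direction and magnitude as
parameters rather than resolving it.

What the generator does **not** emulate: 1/f spectra, volume
conduction, inter-channel correlation structure, non-stationarity
within a trial, or any physiological difference beyond a global
amplitude scaling. Passing tests on this data demonstrate that the
pipeline's machinery works and that its stages compose correctly — not
that the feature set separates real normal from alcoholic EEG.
Cross-validated accuracies near 100% on the synthetic classes reflect
the generator's deliberately strong contrast.

# Problem sizes and reproducibility

The test suite and the acceptance script run at the study's structural
scale where that is cheap (240 x 34 feature matrices, 10-fold splits,
2048-sample epochs) and at reduced scale for iterative classifiers in
unit tests (smaller epochs, the fast grnn classifier) to keep the suite
quick. Oracle-equivalence checks use N = 16 transforms and 50-point
clouds, where the literal O(N^2) and brute-force references are exact.
Every random draw flows from an explicit integer seed; the pipeline
derives per-stage seeds by a stable hash of the stage name, so stages
are independently reproducible.

# Known limitations

* The `"complex"` chirp convention is limited to N <= 32 by double
  precision; production lengths use the pure-phase kernel, which is a
  deliberate deviation from the literal filter definition.
* ReliefF is O(m^2) in the sample count; fine at m = 240, not tuned for
  large corpora.
* The EEG reader handles the plaintext single-trial format only; EDF or
  the full 122-subject archive layout are out of scope.
* Classifier training is plain full-batch gradient descent; no
  momentum, regularization or early stopping. With strongly separable
  synthetic features this is sufficient, and determinism was valued
  over optimizer sophistication.
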