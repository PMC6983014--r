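---
title: "Hybrid filter–wrapper feature selection for inertial activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid filter–wrapper feature selection for inertial activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harsel)
```

## The problem

A waist-mounted smartphone records tri-axial accelerometer and gyroscope
streams at 50 Hz while a person walks, sits, stands, or transitions between
postures. Labeling those streams by activity is a supervised classification
problem, and the conventional approach summarizes fixed-length signal
windows by banks of statistical features. The bank implemented here
computes 23 base statistics on each of the six channels — 138 features per
window — covering time-domain moments (mean, standard deviation, median,
extremes, interquartile range), shape ratios (crest, impulse, margin and
shape factors, square-root amplitude), pairing statistics (a correlation
coefficient with the cyclic neighbour axis of the same sensor, and a cross
correlation with the same axis of the other sensor), and spectral centroid
statistics (frequency center, RMS frequency, root variance frequency).

Most of those 138 columns are redundant or irrelevant for any particular
classification task, and high-dimensional inputs cost both accuracy and
computation on-device. The package's core is a hybrid feature-selection
pipeline that prunes the bank per sensor axis before a final multiclass
classifier is trained.

## The selection model

**Filter stage.** For each axis, sequential floating forward search (SFFS)
maximizes a discriminant feature-distribution objective over that axis's
23 features. The objective z-scores the candidate columns, finds each
class's *median sample* (the sample with the least cumulated Euclidean
distance to its classmates), measures *within-class compactness* as the
distance from the median to the farthest classmate (outliers deliberately
included — dropping them would shrink the class boundary), and
*between-class distance* as the minimum cross-pair distance between two
classes. The objective is the ratio

$$J = \frac{\min_{\text{class pairs}}\ \text{between-class distance}}
          {\max_{\text{classes}}\ \text{within-class compactness}},$$

so maximizing it widens the worst-separated pair relative to the loosest
class. The worst-case aggregation is a deliberate choice (a per-class
average is available via `aggregate = "mean"`): averages can hide one
overlapping pair behind many well-separated ones.

The non-validation data are halved into a filter part and a wrapper test
part, the filter part halved again, and SFFS run independently on each
half; with the default five iterations of fresh random halves this yields
2 × 5 = 10 candidate subsets per axis, 60 overall.

**Wrapper stage.** Every candidate is scored by training a one-against-all
(OAA) linear-kernel soft-margin SVM on its iteration's filter halves and
measuring accuracy on that iteration's wrapper test half. The most
accurate candidate wins its axis (ties prefer smaller subsets, then
lexicographically smaller indices). The six per-axis winners are unioned
and, by default, compressed once more by a second SFFS whose criterion is
the *mean* wrapper accuracy across all five iteration splits — averaging
keeps this refinement from saturating on, or overfitting, any single test
half. The final model is trained on all non-validation windows and
evaluated on the untouched validation half, alongside an all-138-features
baseline.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_len`, `step` | 128, 64 samples | 2.56 s windows, 50% overlap at 50 Hz — the convention of the public smartphone datasets; the source literature does not fix a windowing, so both are configurable |
| `n_iterations` | 5 | filter iterations; 2 candidates per axis each |
| `d_max` | 8 | SFFS size cap; published per-axis optima contain 6–8 features |
| `min_improvement` | 1e-9 | float-noise guard on SFFS inclusions |
| `C`, `kernel` | 1, linear | SVM cost and kernel; the linear kernel is the validated default, RBF selectable |
| `val_fraction`, `filter_fraction` | 0.5, 0.5 | split geometry: half for validation, half of the rest for the filter |
| `aggregate` | "worst" | objective aggregation over classes/pairs |
| `refine` | TRUE | wrapper-driven SFFS over the union of per-axis winners |

## Numerical conventions

Several printed formulas in the source literature for this feature bank are
garbled; the package standardizes them: the median is the plain sample
median (the grouped-frequency form is meaningless for raw samples), SRA is
the square-root amplitude $(\mathbb{E}\sqrt{|x|})^2$ (the established
companion of the margin factor), and the two spectral dispersion features
are the spectral centroid and the power-weighted standard deviation around
it, computed on the DC-removed one-sided periodogram so a gravity offset
cannot dominate the centroid. The peak used by the crest, impulse and
margin factors is $\max|x|$, making them sign-invariant. Standard
deviation uses the $N-1$ denominator while variance, skewness and kurtosis
use population ($1/N$) forms, and kurtosis is non-excess — matching the
printed formula set. Zero-denominator degeneracies (constant or all-zero
windows) return 0 rather than NaN so downstream distances stay finite; the
first such resolution per session is reported via `message()`.

Features are z-scored before distance computations because the bank mixes
units (g, rad/s, Hz, squared units); raw-scale Euclidean distances would be
dominated by large-unit columns. Perfectly compact, separated classes give
a zero denominator; a large finite sentinel (1e12) keeps SFFS comparisons
total. Ties in every argmax break to the lowest index, making the whole
pipeline deterministic given data, configuration and seed.

One subtle degeneracy is worth recording: in one dimension with an even
class size, the cumulated-distance profile is flat between the two middle
samples, so the class median is analytically tied and floating-point
rounding decides between tied candidates. The oracle-agreement tests
therefore compare implementations in two or more dimensions, where such
ties have probability zero.

## The synthetic data generator

Because the public dataset cannot be bundled, the package ships a seeded
generator whose output exercises every pipeline stage. Each activity is,
per channel, DC offset + harmonic oscillation (a base sinusoid plus a 0.6×
second harmonic with independent random phases per bout) + i.i.d. Gaussian
noise + Poisson-timed single-sample impulses. The default palette builds
classes in pairs of three archetypes, chosen so that each planted feature
family is *necessary*:

* two **posture** classes differ only in DC level — only location
  statistics separate them (planted: mean, `f_1`);
* two **gait** classes share almost the same DC (0.1 apart) but differ
  strongly in oscillation amplitude — only scale statistics separate them
  (planted: standard deviation, `f_2`);
* two **transition** classes share almost the same DC and carry
  random-sign impulse trains of *equal power* (rate × amplitude²) but
  different amplitude — their means, variances and spectra coincide and
  only tail-weight statistics separate them (planted: kurtosis, `f_9`).

Three further design details sharpen the attribution. Per-class noise
scales with oscillation amplitude, so scale-free shape statistics (crest,
shape factor, spectral shape) coincide across the non-impulsive classes
instead of acting as accidental super-features. The second harmonic's
random relative phase makes quantile-based statistics (median, IQR) visibly
noisier than the moment statistics they compete with, reflecting their
higher sampling variance on oscillatory signals. The bout-level noise
jitter (±30%) emulates session-to-session noise-floor drift and widens the
clouds of purely spectral features. Base frequencies fit a whole number of
cycles into the default window, so window means and variances are
phase-invariant — the planted features are clean by construction.

Default problem size: 6 classes × 8 bouts × 10 s at 50 Hz — 24 000 samples
per channel, 288 windows. This keeps a full pipeline run around ten
seconds so that seeded replication studies (20 runs) finish in minutes;
the class structure, not the sample count, is what the recovery properties
depend on.

What the generator does **not** emulate: autocorrelated sensor noise,
gravity/body-acceleration mixing, inter-subject variability, drifting
baselines within a bout, or biomechanically realistic waveforms. Passing
the recovery tests therefore demonstrates that the pipeline finds planted
discriminative structure under controlled conditions; it does not certify
accuracy on real recordings, for which the optional integration script
against the public dataset exists (`inst/scripts/uci_hapt_integration.R`,
download required).

## Design choices on open points

* **Correlation partners.** The bank assigns a correlation feature to each
  single axis without naming its partner; the package pairs `f_7` with the
  cyclic successor within the sensor (x→y, y→z, z→x) and `f_10` with the
  same axis of the other sensor. Any fixed convention keeps 23 features
  per channel; this one keeps both features local to the axis's sensor
  context.
* **Wrapper training data.** Candidates are trained on both filter halves
  combined: it maximizes training data without touching the wrapper test
  half.
* **Refinement.** The published final six-feature set is a strict subset
  of the per-axis union with no stated reduction procedure; the package
  implements refinement as a wrapper-accuracy SFFS over the union
  (default on, `refine = FALSE` returns the plain union).
* **Validation split.** Grouped by recording session (`group =
  "experiment"`) when session metadata exists — mirroring
  second-recording-held-out protocols — else stratified random.
* **Filter versus wrapper criterion.** The search algorithm is criterion-
  agnostic; the filter stage plugs in the distribution objective and the
  wrapper/refine stages plug in SVM accuracy, matching the filter/wrapper
  vocabulary of the approach.

## Known limitations

* The SFFS stop rule (no inclusion improving the criterion by at least
  `min_improvement`) halts at the first local maximum of the floating
  path; it does not guarantee the global optimum, and the test suite
  checks optimality only in distribution over random problems.
* The objective is O(n²) in windows per evaluation; filter halves are kept
  small by the split geometry, but very large datasets would need
  subsampling in the filter stage.
* One-against-all decision values from independently trained binary SVMs
  are compared without calibration; with few classes and standardized
  inputs this is standard practice, but probability estimates are out of
  scope.
* Determinism holds given a fixed BLAS and platform; byte-identical JSON
  across heterogeneous hardware is not promised, only across runs on the
  same machine.
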