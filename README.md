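# harsel

Hybrid filter–wrapper feature selection for smartphone-sensor human
activity recognition (HAR).

Waist-mounted smartphones record tri-axial accelerometer and gyroscope
streams at 50 Hz; classifying activities (walking, sitting, postural
transitions, …) from those streams conventionally starts from a large bank
of per-window statistical features, most of which are redundant. `harsel`
implements the full pipeline for pruning that bank and validating the
result:

* **I/O and windowing** — reads raw fixed-column text recordings with
  interval activity labels (the dialect of the public smartphone HAR
  datasets) and segments labeled intervals into fixed-length overlapping
  windows (default 128 samples / 2.56 s, 50% overlap).
* **Feature bank** — 23 base statistics per channel × 6 channels = 138
  named features (`A_x f_1` … `G_z f_23`): moments, quantiles, extremes,
  crest/impulse/margin/shape factors, square-root amplitude, energy, two
  pairing correlations, and three spectral centroid statistics.
* **Filter stage** — per sensor axis, sequential floating forward search
  (SFFS) maximizes a discriminant feature-distribution objective

  `J = min over class pairs of between-class distance / max over classes of within-class compactness`

  where a class's compactness is the Euclidean distance from its median
  sample (least cumulated distance to classmates) to its farthest
  classmate, and between-class distance is the minimum cross-pair gap.
  Five iterations of fresh random data halves yield 10 candidate subsets
  per axis, 60 overall.
* **Wrapper stage** — each candidate is scored by the test accuracy of a
  one-against-all linear-kernel SVM; the best candidate per axis wins, the
  six winners are unioned and refined by a second, accuracy-driven SFFS.
* **Validation** — the final subset is trained on all non-validation
  windows and evaluated on a held-out half, against the all-features
  baseline, with full confusion matrices (recall/precision margins).
* **Synthetic data** — a seeded generator of multi-class six-channel
  recordings with planted discriminative structure (DC levels, oscillation
  amplitudes, impulse regimes), so the entire pipeline is exercisable and
  testable without downloading anything.

## Worked example

```r
library(harsel)

cfg_sim <- default_har_simconfig(n_classes = 6, seed = 1)
rec <- generate_recording(cfg_sim)       # 24 000 samples x 6 channels
ws  <- window_recording(rec)             # 288 labeled windows
fm  <- extract_features(ws)              # 288 x 138 feature matrix

res <- run_pipeline(fm, har_config(seed = 1))
print(res)
```

```
hybrid feature-selection pipeline result
  windows: 288; candidates: 10 per axis (60 total)
  A_x best subset {f_1, f_2, f_6, f_9, f_11, f_12, f_15}, wrapper accuracy 1.0000
  A_y best subset {f_1, f_6, f_9, f_11, f_23}, wrapper accuracy 1.0000
  A_z best subset {f_1, f_2, f_9, f_12, f_13}, wrapper accuracy 1.0000
  G_x best subset {f_1, f_6, f_9, f_11, f_13}, wrapper accuracy 0.9861
  G_y best subset {f_1, f_9, f_11, f_12}, wrapper accuracy 1.0000
  G_z best subset {f_1, f_2, f_6, f_9, f_13}, wrapper accuracy 1.0000
  final set (3): A_x f_12, A_y f_9, G_z f_13
  validation accuracy: 0.9792 with selection, 1.0000 without
```

Each axis's winning subset concentrates on the planted structure of the
synthetic palette — the mean (`f_1`) separating posture levels, spread
statistics (`f_2`, `f_6`, `f_12`) separating gait intensities, and the
kurtosis (`f_9`) separating impulse regimes — and the refined
three-feature set classifies the held-out half within two points of the
138-feature baseline at 2% of its dimensionality.

The command-line interface mirrors the same flow:

```sh
inst/cli/harsel simulate -o rawdir/
inst/cli/harsel extract --raw-dir rawdir/ -o features.csv
inst/cli/harsel select --features features.csv -o result.json
inst/cli/harsel validate --result result.json --features features.csv
```

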