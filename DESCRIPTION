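Package: harsel
Title: Hybrid Filter-Wrapper Feature Selection for Smartphone-Sensor Activity
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for recognising human activities from waist-mounted
    smartphone inertial sensors. Reads raw tri-axial accelerometer and
    gyroscope recordings with interval activity labels, segments them into
    fixed-length overlapping windows, and computes a 138-dimensional bank of
    time- and frequency-domain statistical features (23 base features per
    channel). Feature subsets are selected per sensor axis by a hybrid
    scheme: sequential floating forward search (SFFS) driven by a
    discriminant feature-distribution objective (within-class compactness
    versus between-class distance) in the filter stage, followed by a
    one-against-all linear support vector machine wrapper that picks the
    best candidate set per axis. The per-axis winners are combined,
    optionally refined, and validated on held-out data. A seeded generator
    of multi-class synthetic recordings with planted discriminative
    structure makes the whole pipeline testable without any external
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
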