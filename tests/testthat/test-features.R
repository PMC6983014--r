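test_that("feature naming covers 138 columns in canonical order", {
  nm <- har_feature_names()
  expect_length(nm, 138L)
  expect_identical(anyDuplicated(nm), 0L)
  expect_identical(nm[1L], "A_x f_1")
  expect_identical(nm[7L], "A_x f_7")      # correlation coefficient slot
  expect_identical(nm[24L], "A_y f_1")
  expect_identical(nm[138L], "G_z f_23")
  expect_identical(har_base_features()$feature[7L], "Correlation coefficient")
  expect_identical(har_base_features()$feature[13L], "Root Mean Square")
})

test_that("simple time-domain features match hand values", {
  expect_equal(time_feature("mean", c(1, 2, 3)), 2)
  expect_equal(time_feature("variance", c(1, 2, 3)), 2 / 3)
  expect_equal(time_feature("std", c(1, 2, 3)), 1)
  expect_equal(time_feature("energy", c(1, 2)), 5)
  expect_equal(time_feature("rms", c(3, 3, 3, 3)), 3)
  expect_equal(time_feature("crest_factor", rep(2, 10)), 1)
  expect_equal(time_feature("shape_factor", rep(-5, 10)), 1)
})

test_that("degenerate inputs resolve to zero, not NaN", {
  cst <- rep(4, 16)
  expect_equal(time_feature("skewness", cst), 0)
  expect_equal(time_feature("kurtosis", cst), 0)
  expect_equal(time_feature("correlation", cst, rnorm(16)), 0)
  zero <- rep(0, 16)
  for (k in c("crest_factor", "impulse_factor", "margin_factor",
              "shape_factor"))
    expect_equal(time_feature(k, zero), 0)
  w <- toy_window(matrix(0, 128, 6))
  v <- extract_window_features(w)
  expect_true(all(is.finite(v)))
  expect_true(all(v == 0))
})

test_that("time features agree with naive-loop oracles on random series", {
  kinds <- setdiff(harsel:::.time_feature_kinds,
                   c("correlation", "cross_correlation"))
  harsel:::.with_seed(7L, {
    for (i in 1:100) {
      x <- rnorm(sample(16:256, 1L), sd = runif(1, 0.1, 5))
      p <- rnorm(length(x))
      for (k in kinds)
        expect_equal(time_feature(k, x), oracle_time_feature(k, x),
                     tolerance = 1e-9)
      expect_equal(time_feature("correlation", x, p),
                   oracle_time_feature("correlation", x, p),
                   tolerance = 1e-9)
    }
  })
})

test_that("spectral features match a brute-force DFT and known signals", {
  fs <- 50
  n <- 128L
  t <- (0:(n - 1L)) / fs
  # pure sinusoid on an exact bin: centroid at f0, zero spread
  f0 <- 10 * fs / n
  x <- sin(2 * pi * f0 * t + 0.3)
  sp <- spectral_features(x, fs)
  expect_equal(unname(sp["frequency_center"]), f0, tolerance = 1e-9)
  expect_equal(unname(sp["root_variance_frequency"]), 0, tolerance = 1e-6)
  # constant series carries no spectral power
  expect_equal(unname(spectral_features(rep(3, n), fs)), c(0, 0, 0))
  # random series vs O(n^2) DFT oracle
  harsel:::.with_seed(11L, {
    for (i in 1:20) {
      x <- rnorm(sample(c(32L, 64L, 100L), 1L))
      got <- unname(spectral_features(x, fs))
      expect_equal(got, oracle_spectral(x, fs), tolerance = 1e-9)
    }
  })
})

test_that("moment and spectral identities hold on random series", {
  harsel:::.with_seed(13L, {
    for (i in 1:50) {
      x <- rnorm(128, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
      rms <- time_feature("rms", x)
      expect_equal(rms^2,
                   time_feature("variance", x) + time_feature("mean", x)^2,
                   tolerance = 1e-9)
      sp <- spectral_features(x, 50)
      expect_equal(unname(sp["rms_frequency"]^2),
                   unname(sp["frequency_center"]^2 +
                            sp["root_variance_frequency"]^2),
                   tolerance = 1e-9)
    }
  })
})

test_that("features scale as dimensional analysis dictates", {
  harsel:::.with_seed(17L, {
    x <- rnorm(128, 1, 2)
    c_ <- 3.7
    linear <- c("mean", "std", "median", "max", "min", "iqr", "abs_mean",
                "rms", "ppv")
    for (k in linear)
      expect_equal(time_feature(k, c_ * x), c_ * time_feature(k, x),
                   tolerance = 1e-9)
    expect_equal(time_feature("energy", c_ * x),
                 c_^2 * time_feature("energy", x), tolerance = 1e-9)
    invariant <- c("skewness", "kurtosis", "crest_factor", "impulse_factor",
                   "shape_factor")
    for (k in invariant)
      expect_equal(time_feature(k, c_ * x), time_feature(k, x),
                   tolerance = 1e-9)
    p <- rnorm(128)
    expect_equal(time_feature("correlation", c_ * x, p),
                 time_feature("correlation", x, p), tolerance = 1e-9)
    expect_equal(unname(spectral_features(c_ * x, 50)["frequency_center"]),
                 unname(spectral_features(x, 50)["frequency_center"]),
                 tolerance = 1e-9)
  })
})

test_that("a window maps to 138 finite named features with sparse support", {
  w <- random_window()
  v <- extract_window_features(w)
  expect_length(v, 138L)
  expect_identical(names(v), har_feature_names())
  expect_true(all(is.finite(v)))

  # only acc_x nonzero: its own features and the pairing features touching
  # acc_x may be nonzero; everything else must be zero
  m <- matrix(0, 128, 6)
  m[, 1] <- seq_len(128)
  v2 <- extract_window_features(toy_window(m))
  nonzero <- names(v2)[v2 != 0]
  expect_true(all(grepl("^A_x ", nonzero)))
})

test_that("feature matrices extract and round-trip through CSV", {
  rec <- toy_recording(T = 600L, intervals = data.frame(
    activity_id = c(1L, 2L), start_sample = c(1L, 301L),
    end_sample = c(300L, 600L)))
  fm <- extract_features(window_recording(rec, 64L, 64L))
  expect_identical(dim(fm$x), c(8L, 138L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fm, path)
  back <- read_features_csv(path)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_identical(back$label, fm$label)
})
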