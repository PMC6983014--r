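#' @importFrom stats fft median quantile sd
NULL

# One-shot notice when a zero-denominator degeneracy is resolved to 0.
.harsel_state <- new.env(parent = emptyenv())

.degenerate_zero <- function(what) {
  if (!isTRUE(.harsel_state$degeneracy_notified)) {
    .harsel_state$degeneracy_notified <- TRUE
    message("harsel: zero-denominator feature degeneracy (", what,
            ") resolved to 0; further occurrences this run are silent")
  }
  0
}

.channel_order <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")

.base_feature_labels <- c(
  "Mean", "Standard Deviation", "Median", "Maximum", "Minimum",
  "Interquartile Range", "Correlation coefficient", "Skewness", "Kurtosis",
  "Cross Correlation", "Mean Absolute Value", "Variance", "Root Mean Square",
  "Energy", "SRA", "Peak to Peak", "Crest Factor", "Impulse Factor",
  "Margin Factor", "Shape Factor", "Frequency Center", "RMS Frequency",
  "Root Variant Frequency")

.time_feature_kinds <- c(
  "mean", "std", "median", "max", "min", "iqr", "correlation", "skewness",
  "kurtosis", "cross_correlation", "abs_mean", "variance", "rms", "energy",
  "sra", "ppv", "crest_factor", "impulse_factor", "margin_factor",
  "shape_factor")

#' Names of the 138-dimensional feature bank
#'
#' 23 base statistical features on each of the six channels, ordered channel
#' by channel (all of acc-x, then acc-y, acc-z, gyro-x, gyro-y, gyro-z) and
#' rendered in the conventional `"A_x f_1"` ... `"G_z f_23"` notation
#' (sensor A = accelerometer, G = gyroscope).
#'
#' @return character vector of length 138.
#' @export
har_feature_names <- function() {
  sensors <- c(acc = "A", gyro = "G")
  out <- character(0)
  for (ch in .channel_order) {
    parts <- strsplit(ch, "_", fixed = TRUE)[[1L]]
    out <- c(out, sprintf("%s_%s f_%d", sensors[[parts[1L]]], parts[2L], 1:23))
  }
  out
}

#' Descriptions of the 23 base features
#'
#' @return data frame with columns `index` (1..23) and `feature` (the
#'   conventional name of each base statistic).
#' @export
har_base_features <- function() {
  data.frame(index = 1:23, feature = .base_feature_labels)
}

#' Compute one time-domain statistical feature of a series
#'
#' Conventions: standard deviation uses the N-1 denominator while variance,
#' skewness and kurtosis use the population (1/N) forms; kurtosis is
#' non-excess; quantiles are linearly interpolated; the peak used by the
#' crest, impulse and margin factors is `max(abs(x))`; SRA (square-root
#' amplitude) is `(mean(sqrt(abs(x))))^2`. Any zero-denominator degeneracy
#' (constant series, all-zero series) returns 0 so downstream distance
#' computations stay finite.
#'
#' @param kind one of `"mean"`, `"std"`, `"median"`, `"max"`, `"min"`,
#'   `"iqr"`, `"correlation"`, `"skewness"`, `"kurtosis"`,
#'   `"cross_correlation"`, `"abs_mean"`, `"variance"`, `"rms"`, `"energy"`,
#'   `"sra"`, `"ppv"`, `"crest_factor"`, `"impulse_factor"`,
#'   `"margin_factor"`, `"shape_factor"`.
#' @param x numeric series of length >= 2.
#' @param partner second series of equal length, required for
#'   `"correlation"` and `"cross_correlation"`.
#' @return a single numeric value.
#' @export
time_feature <- function(kind, x, partner = NULL) {
  kind <- match.arg(kind, .time_feature_kinds)
  n <- length(x)
  if (n < 2L) stop("series must have length >= 2")
  if (kind %in% c("correlation", "cross_correlation")) {
    if (is.null(partner)) stop(kind, " requires a partner series")
    if (length(partner) != n) stop("partner length differs from x")
    sx <- sqrt(mean((x - mean(x))^2))
    sy <- sqrt(mean((partner - mean(partner))^2))
    if (sx == 0 || sy == 0) return(.degenerate_zero(kind))
    # cov/(sd_x sd_y) with matched (population) denominators: Pearson r
    return(mean((x - mean(x)) * (partner - mean(partner))) / (sx * sy))
  }
  switch(kind,
    mean = mean(x),
    std = sd(x),
    median = median(x),
    max = max(x),
    min = min(x),
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    skewness = {
      s <- sqrt(mean((x - mean(x))^2))
      if (s == 0) .degenerate_zero("skewness")
      else mean(((x - mean(x)) / s)^3)
    },
    kurtosis = {
      s <- sqrt(mean((x - mean(x))^2))
      if (s == 0) .degenerate_zero("kurtosis")
      else mean(((x - mean(x)) / s)^4)
    },
    abs_mean = mean(abs(x)),
    variance = mean((x - mean(x))^2),
    rms = sqrt(mean(x^2)),
    energy = sum(abs(x)^2),
    sra = mean(sqrt(abs(x)))^2,
    ppv = max(x) - min(x),
    crest_factor = {
      r <- sqrt(mean(x^2))
      if (r == 0) .degenerate_zero("crest_factor") else max(abs(x)) / r
    },
    impulse_factor = {
      a <- mean(abs(x))
      if (a == 0) .degenerate_zero("impulse_factor") else max(abs(x)) / a
    },
    margin_factor = {
      s <- mean(sqrt(abs(x)))^2
      if (s == 0) .degenerate_zero("margin_factor") else max(abs(x)) / s
    },
    shape_factor = {
      a <- mean(abs(x))
      if (a == 0) .degenerate_zero("shape_factor") else sqrt(mean(x^2)) / a
    })
}

#' Spectral centroid features of a series
#'
#' The series is mean-removed, its one-sided power spectrum `P_k =
#' |FFT(x - mean(x))|^2` taken over bins `k = 1..floor(N/2)` (DC excluded,
#' so a gravity offset cannot dominate), with bin frequencies `f_k = k *
#' fs / N`. Frequency center is the power-weighted mean frequency, RMS
#' frequency the power-weighted root mean square frequency, and root
#' variance frequency the power-weighted standard deviation around the
#' center. All three are 0 when the spectrum carries no power.
#'
#' @param x numeric series, length >= 8.
#' @param sample_rate_hz sampling rate in Hz.
#' @return named numeric vector `c(frequency_center, rms_frequency,
#'   root_variance_frequency)`, in Hz.
#' @export
spectral_features <- function(x, sample_rate_hz) {
  n <- length(x)
  if (n < 8L) stop("series must have length >= 8")
  k <- seq_len(n %/% 2L)
  P <- Mod(fft(x - mean(x)))[k + 1L]^2
  f <- k * sample_rate_hz / n
  tot <- sum(P)
  if (tot == 0)
    return(c(frequency_center = 0, rms_frequency = 0,
             root_variance_frequency = 0))
  fc <- sum(f * P) / tot
  rmsf <- sqrt(sum(f^2 * P) / tot)
  rvf <- sqrt(sum((f - fc)^2 * P) / tot)
  c(frequency_center = fc, rms_frequency = rmsf,
    root_variance_frequency = rvf)
}

# correlation partner (f_7): cyclic successor within the same sensor
.corr_partner <- c(acc_x = "acc_y", acc_y = "acc_z", acc_z = "acc_x",
                   gyro_x = "gyro_y", gyro_y = "gyro_z", gyro_z = "gyro_x")
# cross-correlation partner (f_10): same axis of the other sensor
.cross_partner <- c(acc_x = "gyro_x", acc_y = "gyro_y", acc_z = "gyro_z",
                    gyro_x = "acc_x", gyro_y = "acc_y", gyro_z = "acc_z")

.channel_features <- function(ch_name, sig, sample_rate_hz) {
  x <- sig[, ch_name]
  sp <- spectral_features(x, sample_rate_hz)
  c(time_feature("mean", x),
    time_feature("std", x),
    time_feature("median", x),
    time_feature("max", x),
    time_feature("min", x),
    time_feature("iqr", x),
    time_feature("correlation", x, sig[, .corr_partner[[ch_name]]]),
    time_feature("skewness", x),
    time_feature("kurtosis", x),
    time_feature("cross_correlation", x, sig[, .cross_partner[[ch_name]]]),
    time_feature("abs_mean", x),
    time_feature("variance", x),
    time_feature("rms", x),
    time_feature("energy", x),
    time_feature("sra", x),
    time_feature("ppv", x),
    time_feature("crest_factor", x),
    time_feature("impulse_factor", x),
    time_feature("margin_factor", x),
    time_feature("shape_factor", x),
    unname(sp))
}

#' Extract the 138-dimensional feature vector of one window
#'
#' Computes all 23 base features on each of the six channels, in the
#' canonical order returned by [har_feature_names()]. The two pairing
#' features use fixed partners: the correlation coefficient (f_7) pairs a
#' channel with its cyclic successor within the same sensor (x to y, y to z,
#' z to x); the cross correlation (f_10) pairs it with the same axis of the
#' other sensor.
#'
#' @param w a `signal_window` from [window_recording()].
#' @return named numeric vector of length 138; all values finite.
#' @export
extract_window_features <- function(w) {
  stopifnot(inherits(w, "signal_window"))
  v <- unlist(lapply(.channel_order, .channel_features,
                     sig = w$channels, sample_rate_hz = w$sample_rate_hz),
              use.names = FALSE)
  names(v) <- har_feature_names()
  v
}

#' Extract the feature matrix of a window set
#'
#' @param ws a `window_set`.
#' @return An object of class `har_features`: list with `x` (numeric matrix,
#'   windows x 138, columns named per [har_feature_names()]), `label`
#'   (integer activity ids), `meta` (window provenance data frame), and
#'   `activity_names`.
#' @export
extract_features <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  if (!length(ws$windows)) stop("window set is empty")
  x <- t(vapply(ws$windows, extract_window_features,
                numeric(138L)))
  meta <- data.frame(
    experiment_id = vapply(ws$windows, `[[`, integer(1L), "experiment_id"),
    user_id = vapply(ws$windows, `[[`, integer(1L), "user_id"),
    start_sample = vapply(ws$windows, `[[`, integer(1L), "start_sample"))
  structure(list(x = x, label = window_labels(ws), meta = meta,
                 activity_names = ws$activity_names),
            class = "har_features")
}

#' @export
print.har_features <- function(x, ...) {
  cat(sprintf("har_features: %d windows x %d features, %d activities\n",
              nrow(x$x), ncol(x$x), length(unique(x$label))))
  invisible(x)
}

#' Write a feature matrix to CSV
#'
#' One row per window: the 138 feature columns named per
#' [har_feature_names()], then provenance columns, then a trailing `label`
#' column.
#'
#' @param fm a `har_features` object.
#' @param path output CSV path.
#' @export
write_features_csv <- function(fm, path) {
  stopifnot(inherits(fm, "har_features"))
  d <- as.data.frame(fm$x, check.names = FALSE)
  d <- cbind(d, fm$meta, label = fm$label)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features_csv()]
#'
#' @param path CSV path.
#' @return a `har_features` object.
#' @export
read_features_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  fn <- har_feature_names()
  if (!all(fn %in% names(d)))
    stop("CSV is missing feature columns; expected the 138 canonical names")
  meta_cols <- intersect(c("experiment_id", "user_id", "start_sample"),
                         names(d))
  structure(list(x = as.matrix(d[, fn]),
                 label = as.integer(d$label),
                 meta = d[, meta_cols, drop = FALSE],
                 activity_names = NULL),
            class = "har_features")
}

#' Subset the rows of a feature matrix
#' @param fm a `har_features` object.
#' @param idx integer row indices.
#' @return a `har_features` with the selected windows.
#' @export
features_rows <- function(fm, idx) {
  structure(list(x = fm$x[idx, , drop = FALSE], label = fm$label[idx],
                 meta = fm$meta[idx, , drop = FALSE],
                 activity_names = fm$activity_names),
            class = "har_features")
}
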