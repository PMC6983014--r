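#' Construct a labeled six-channel recording
#'
#' A labeled recording holds a continuous tri-axial accelerometer trace, a
#' tri-axial gyroscope trace of identical length, and a set of activity
#' intervals. Intervals are 1-based and inclusive at both ends, the dialect
#' used by the public smartphone activity datasets; samples outside any
#' interval are legal and simply never contribute windows.
#'
#' @param acc numeric matrix with three columns (x, y, z), one row per sample,
#'   in g or m/s^2.
#' @param gyro numeric matrix with three columns (x, y, z), same row count as
#'   `acc`, in rad/s.
#' @param intervals data frame with integer columns `activity_id`,
#'   `start_sample`, `end_sample` (1-based, inclusive). May have zero rows.
#' @param sample_rate_hz positive sampling rate, default 50.
#' @param experiment_id,user_id integer identifiers carried into window
#'   provenance.
#' @return An object of class `labeled_recording`.
#' @export
labeled_recording <- function(acc, gyro, intervals,
                              sample_rate_hz = 50,
                              experiment_id = 1L, user_id = 1L) {
  acc <- as.matrix(acc)
  gyro <- as.matrix(gyro)
  if (ncol(acc) != 3L || ncol(gyro) != 3L)
    stop("acc and gyro must each have exactly 3 columns (x, y, z)")
  if (nrow(acc) != nrow(gyro))
    stop(sprintf("acc and gyro lengths differ (%d vs %d samples)",
                 nrow(acc), nrow(gyro)))
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0)
    stop("sample_rate_hz must be a single positive number")
  storage.mode(acc) <- "double"
  storage.mode(gyro) <- "double"
  colnames(acc) <- c("x", "y", "z")
  colnames(gyro) <- c("x", "y", "z")
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) > 0L) {
    need <- c("activity_id", "start_sample", "end_sample")
    if (!all(need %in% names(intervals)))
      stop("intervals must have columns activity_id, start_sample, end_sample")
    intervals <- intervals[, need, drop = FALSE]
    T <- nrow(acc)
    bad <- which(intervals$start_sample < 1L |
                   intervals$end_sample > T |
                   intervals$start_sample > intervals$end_sample)
    if (length(bad))
      stop(sprintf(
        "interval %d (activity %d, samples %d..%d) out of range for T=%d",
        bad[1L], intervals$activity_id[bad[1L]],
        intervals$start_sample[bad[1L]], intervals$end_sample[bad[1L]], T))
  } else {
    intervals <- data.frame(activity_id = integer(),
                            start_sample = integer(),
                            end_sample = integer())
  }
  structure(
    list(acc = acc, gyro = gyro, intervals = intervals,
         sample_rate_hz = sample_rate_hz,
         experiment_id = as.integer(experiment_id),
         user_id = as.integer(user_id)),
    class = "labeled_recording")
}

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf(
    "labeled_recording: experiment %d, user %d, %d samples @ %g Hz, %d intervals (%d activities)\n",
    x$experiment_id, x$user_id, nrow(x$acc), x$sample_rate_hz,
    nrow(x$intervals), length(unique(x$intervals$activity_id))))
  invisible(x)
}

.read_signal_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  con <- textConnection(lines)
  on.exit(close(con))
  m <- tryCatch(
    scan(con, what = double(), quiet = TRUE),
    error = function(e) NULL)
  if (is.null(m) || length(m) %% 3L != 0L) {
    # locate the offending line for the error message
    for (i in seq_along(lines)) {
      f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
      if (length(f) != 3L || anyNA(suppressWarnings(as.numeric(f))))
        stop(sprintf("%s: line %d is not three numeric fields: '%s'",
                     path, i, lines[i]))
    }
    stop(sprintf("%s: malformed signal file", path))
  }
  matrix(m, ncol = 3L, byrow = TRUE)
}

#' Read a raw recording from HAPT-style text files
#'
#' Each signal file carries one sample per line as three whitespace-separated
#' decimal fields; line i is sample i (1-based). The accelerometer and
#' gyroscope files must have equal line counts.
#'
#' @param acc_path,gyro_path paths to the accelerometer and gyroscope files.
#' @param labels data frame of intervals (`activity_id`, `start_sample`,
#'   `end_sample`), e.g. one experiment's slice of [read_labels_file()].
#' @param sample_rate_hz sampling rate, default 50.
#' @param experiment_id,user_id identifiers stored on the recording.
#' @return A [labeled_recording()].
#' @export
read_raw_recording <- function(acc_path, gyro_path, labels,
                               sample_rate_hz = 50,
                               experiment_id = 1L, user_id = 1L) {
  acc <- .read_signal_file(acc_path)
  gyro <- .read_signal_file(gyro_path)
  if (nrow(acc) != nrow(gyro))
    stop(sprintf("line count mismatch: %s has %d samples, %s has %d",
                 acc_path, nrow(acc), gyro_path, nrow(gyro)))
  labeled_recording(acc, gyro, labels, sample_rate_hz,
                    experiment_id = experiment_id, user_id = user_id)
}

#' Read a five-column interval label file
#'
#' Columns: experiment id, user id, activity id, start sample, end sample
#' (whitespace-separated integers, 1-based inclusive sample indices).
#'
#' @param path label file path.
#' @return data frame with columns `experiment_id`, `user_id`, `activity_id`,
#'   `start_sample`, `end_sample`.
#' @export
read_labels_file <- function(path) {
  m <- utils::read.table(path, col.names = c(
    "experiment_id", "user_id", "activity_id", "start_sample", "end_sample"))
  for (cn in names(m)) m[[cn]] <- as.integer(m[[cn]])
  m
}

#' Segment a labeled recording into fixed-length overlapping windows
#'
#' Each labeled interval of length `L >= window_len` yields
#' `floor((L - window_len) / step) + 1` windows, every window lying entirely
#' inside its interval and carrying that interval's activity id. Windows never
#' straddle two intervals; intervals shorter than `window_len` yield nothing,
#' and unlabeled samples are dropped.
#'
#' @param rec a [labeled_recording()].
#' @param window_len window length in samples, >= 8; default 128 (2.56 s at
#'   50 Hz).
#' @param step hop between window starts in samples, `1 <= step <=
#'   window_len`; default 64 (50% overlap).
#' @param activity_names optional named character vector mapping activity ids
#'   to names.
#' @return An object of class `window_set`: a list of windows plus the name
#'   map. Each window has a `channels` matrix (N x 6, columns `acc_x`,
#'   `acc_y`, `acc_z`, `gyro_x`, `gyro_y`, `gyro_z`), a `label`, and
#'   provenance fields.
#' @export
window_recording <- function(rec, window_len = 128L, step = 64L,
                             activity_names = NULL) {
  stopifnot(inherits(rec, "labeled_recording"))
  window_len <- as.integer(window_len)
  step <- as.integer(step)
  if (window_len < 8L) stop("window_len must be >= 8")
  if (step < 1L || step > window_len)
    stop("step must satisfy 1 <= step <= window_len")
  sig <- cbind(rec$acc, rec$gyro)
  colnames(sig) <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  windows <- list()
  iv <- rec$intervals
  for (i in seq_len(nrow(iv))) {
    L <- iv$end_sample[i] - iv$start_sample[i] + 1L
    if (L < window_len) next
    n_win <- (L - window_len) %/% step + 1L
    for (k in seq_len(n_win)) {
      s0 <- iv$start_sample[i] + (k - 1L) * step
      windows[[length(windows) + 1L]] <- structure(
        list(channels = sig[s0:(s0 + window_len - 1L), , drop = FALSE],
             label = iv$activity_id[i],
             experiment_id = rec$experiment_id,
             user_id = rec$user_id,
             start_sample = s0,
             sample_rate_hz = rec$sample_rate_hz),
        class = "signal_window")
    }
  }
  structure(list(windows = windows, activity_names = activity_names,
                 sample_rate_hz = rec$sample_rate_hz),
            class = "window_set")
}

#' Merge several window sets
#'
#' @param ... `window_set` objects (or a single list of them).
#' @return a `window_set` containing all windows in order.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "window_set"))
    sets <- sets[[1L]]
  stopifnot(all(vapply(sets, inherits, logical(1L), "window_set")))
  nm <- NULL
  for (s in sets) if (!is.null(s$activity_names)) nm <- s$activity_names
  structure(list(windows = do.call(c, lapply(sets, `[[`, "windows")),
                 activity_names = nm,
                 sample_rate_hz = sets[[1L]]$sample_rate_hz),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  labs <- vapply(x$windows, `[[`, integer(1L), "label")
  cat(sprintf("window_set: %d windows, %d activities\n",
              length(x$windows), length(unique(labs))))
  if (length(labs)) print(table(activity = labs))
  invisible(x)
}

#' @export
print.signal_window <- function(x, ...) {
  cat(sprintf(
    "signal_window: %d samples x 6 channels, activity %d (exp %d, user %d, start %d)\n",
    nrow(x$channels), x$label, x$experiment_id, x$user_id, x$start_sample))
  invisible(x)
}

#' Labels of a window set
#' @param ws a `window_set`.
#' @return integer vector of activity ids, one per window.
#' @export
window_labels <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  vapply(ws$windows, `[[`, integer(1L), "label")
}
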