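# Run expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.expand6 <- function(v, what) {
  if (length(v) == 1L) v <- rep(v, 6L)
  if (length(v) != 6L)
    stop(what, " must have length 1 or 6 (one value per channel)")
  stats::setNames(as.numeric(v), .channel_order)
}

#' Define one synthetic activity class
#'
#' Each channel of an activity is modelled as DC offset + sinusoids +
#' i.i.d. Gaussian noise + Poisson-timed single-sample impulses. The three
#' ingredients mimic the qualitative contrast between postures (distinct
#' mean levels), gait-like dynamic activities (sustained oscillation), and
#' postural transitions (sparse large spikes).
#'
#' @param activity_id integer class id.
#' @param dc per-channel DC offset; scalar or length-6 vector ordered
#'   `acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z`.
#' @param noise_sd per-channel Gaussian noise standard deviation (scalar or
#'   length 6, nonnegative).
#' @param sinusoids data frame with columns `channel`, `amplitude`,
#'   `frequency_hz` (one row per component; phases are drawn uniformly per
#'   bout), or `NULL` for none.
#' @param impulse_rate per-channel impulse rate in events per second
#'   (scalar or length 6, nonnegative).
#' @param impulse_amp per-channel impulse amplitude added at each event
#'   sample (scalar or length 6).
#' @param impulse_sign `"positive"` (impulses always add `impulse_amp`) or
#'   `"random"` (each event flips a fair coin for its sign, making the
#'   impulse process zero-mean).
#' @param noise_jitter bout-level noise variability: each bout draws its
#'   noise standard deviation uniformly from `noise_sd * (1 +/-
#'   noise_jitter)`, emulating the session-to-session noise-floor drift of
#'   real sensors; default 0 (constant noise).
#' @return an object of class `activity_profile`.
#' @export
activity_profile <- function(activity_id, dc = 0, noise_sd = 0.1,
                             sinusoids = NULL, impulse_rate = 0,
                             impulse_amp = 0,
                             impulse_sign = c("positive", "random"),
                             noise_jitter = 0) {
  impulse_sign <- match.arg(impulse_sign)
  if (noise_jitter < 0 || noise_jitter >= 1)
    stop("noise_jitter must lie in [0, 1)")
  noise_sd <- .expand6(noise_sd, "noise_sd")
  impulse_rate <- .expand6(impulse_rate, "impulse_rate")
  if (any(noise_sd < 0) || any(impulse_rate < 0))
    stop("noise_sd and impulse_rate must be nonnegative")
  if (!is.null(sinusoids)) {
    sinusoids <- as.data.frame(sinusoids)
    need <- c("channel", "amplitude", "frequency_hz")
    if (!all(need %in% names(sinusoids)))
      stop("sinusoids needs columns channel, amplitude, frequency_hz")
    if (!all(sinusoids$channel %in% .channel_order))
      stop("unknown channel in sinusoids")
    if (any(sinusoids$amplitude < 0))
      stop("sinusoid amplitudes must be nonnegative")
  }
  structure(list(activity_id = as.integer(activity_id),
                 dc = .expand6(dc, "dc"),
                 noise_sd = noise_sd,
                 sinusoids = sinusoids,
                 impulse_rate = impulse_rate,
                 impulse_amp = .expand6(impulse_amp, "impulse_amp"),
                 impulse_sign = impulse_sign,
                 noise_jitter = noise_jitter),
            class = "activity_profile")
}

#' Simulation configuration for synthetic recordings
#'
#' @param profiles list of [activity_profile()]s, at least 2.
#' @param seed integer RNG seed; the recording is fully reproducible from it.
#' @param sample_rate_hz sampling rate, default 50.
#' @param bouts_per_activity labeled bouts generated per activity, default 8.
#' @param bout_duration_s duration of each bout in seconds, default 10 (must
#'   cover at least one analysis window).
#' @param planted_features optional named list (one entry per channel) of
#'   base-feature indices (1..23) the configuration plants as
#'   discriminative, used by recovery checks.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(profiles, seed = 1L, sample_rate_hz = 50,
                       bouts_per_activity = 8L, bout_duration_s = 10,
                       planted_features = NULL) {
  if (length(profiles) < 2L) stop("need at least 2 activity profiles")
  stopifnot(all(vapply(profiles, inherits, logical(1L), "activity_profile")))
  for (p in profiles) {
    if (!is.null(p$sinusoids) &&
        any(p$sinusoids$frequency_hz >= sample_rate_hz / 2))
      stop("sinusoid frequency at or above Nyquist for activity ",
           p$activity_id)
  }
  structure(list(profiles = profiles, seed = as.integer(seed),
                 sample_rate_hz = sample_rate_hz,
                 bouts_per_activity = as.integer(bouts_per_activity),
                 bout_duration_s = bout_duration_s,
                 planted_features = planted_features),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d activities x %d bouts x %gs @ %g Hz (seed %d)\n",
    length(x$profiles), x$bouts_per_activity, x$bout_duration_s,
    x$sample_rate_hz, x$seed))
  invisible(x)
}

# per-channel magnitude scaling: accelerometer in g-scale units, gyroscope
# about half that in rad/s, with mild axis-to-axis variation
.axis_scale <- c(acc_x = 1, acc_y = 0.85, acc_z = 1.15,
                 gyro_x = 0.5, gyro_y = 0.425, gyro_z = 0.575)
# sinusoid base frequencies chosen to fit a whole number of cycles into the
# default 2.56 s window, so window means are phase-invariant
.axis_freq <- c(acc_x = 2.734375, acc_y = 2.734375, acc_z = 2.734375,
                gyro_x = 3.125, gyro_y = 3.125, gyro_z = 3.125)

#' Default synthetic activity palette
#'
#' Builds `n_classes` profiles as pairs of three archetypes. Posture pairs
#' sit at distinct DC levels with identical gentle oscillation, so only the
#' signal level tells them apart. Gait pairs share almost the same DC level
#' (a 0.1 gap) but differ strongly in oscillation amplitude, so only the
#' signal spread separates them. Transition pairs share almost the same DC
#' level and carry random-sign Poisson impulse trains of equal power
#' (rate x amplitude^2) but different amplitude, so their variance and
#' spectra coincide and only tail weight separates them. Waveforms carry a
#' second harmonic with an independent phase (making quantile-type
#' statistics noisier than moments), per-class noise scales with
#' oscillation amplitude (so scale-free shape statistics coincide across
#' non-impulsive classes), and the noise floor drifts between bouts. The
#' planted base features per axis are therefore 1 (mean) when several DC
#' levels are present, 2 (standard deviation) when amplitudes differ, and
#' 9 (kurtosis) when impulsive classes are present.
#'
#' @param n_classes number of activities, 2..12; default 6 (mirroring the
#'   six basic activities of public smartphone datasets; 12 mirrors the
#'   full palette with postural transitions).
#' @param seed RNG seed stored in the configuration.
#' @param bouts_per_activity,bout_duration_s passed to [sim_config()].
#' @return a [sim_config()].
#' @export
default_har_simconfig <- function(n_classes = 6L, seed = 1L,
                                  bouts_per_activity = 8L,
                                  bout_duration_s = 10) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L || n_classes > 12L) stop("n_classes must be in 2..12")
  # archetype pairs: (dc, amp, impulse rate, impulse amplitude) per class;
  # successive tiers repeat the block at higher DC
  base_pairs <- list(
    posture = list(c(1.00, 0.50, 0, 0), c(1.45, 0.50, 0, 0)),
    gait = list(c(1.90, 2.20, 0, 0), c(2.00, 1.35, 0, 0)),
    transition = list(c(2.45, 0.50, 8, 1.15), c(2.55, 0.50, 2, 2.30)))
  profiles <- vector("list", n_classes)
  dcs <- amps <- rates <- numeric(n_classes)
  for (i in seq_len(n_classes)) {
    pair <- (i - 1L) %/% 2L
    member <- (i - 1L) %% 2L + 1L
    kind <- pair %% 3L + 1L
    tier <- pair %/% 3L
    p <- base_pairs[[kind]][[member]]
    dc <- p[1L] + 2.0 * tier
    amp <- p[2L] * (1 + 0.3 * tier)
    rate <- p[3L]
    iamp <- p[4L] * (1 + 0.3 * tier)
    dcs[i] <- dc; amps[i] <- amp; rates[i] <- rate
    profiles[[i]] <- activity_profile(
      activity_id = i,
      dc = dc * .axis_scale,
      noise_sd = 0.18 * amp * .axis_scale,
      sinusoids = data.frame(
        channel = rep(.channel_order, 2L),
        amplitude = c(amp * .axis_scale, 0.6 * amp * .axis_scale),
        frequency_hz = c(.axis_freq, 2 * .axis_freq)),
      impulse_rate = rate,
      impulse_amp = iamp * .axis_scale,
      impulse_sign = "random",
      noise_jitter = 0.3)
  }
  planted <- integer(0)
  if (length(unique(dcs)) > 1L) planted <- c(planted, 1L)
  if (length(unique(amps)) > 1L) planted <- c(planted, 2L)
  if (any(rates > 0)) planted <- c(planted, 9L)
  sim_config(profiles, seed = seed,
             bouts_per_activity = bouts_per_activity,
             bout_duration_s = bout_duration_s,
             planted_features = stats::setNames(rep(list(planted), 6L),
                                                .channel_order))
}

.simulate_bout <- function(profile, n, fs) {
  t <- (seq_len(n) - 1L) / fs
  out <- matrix(0, nrow = n, ncol = 6L,
                dimnames = list(NULL, .channel_order))
  for (ch in .channel_order) {
    x <- rep(profile$dc[[ch]], n)
    if (!is.null(profile$sinusoids)) {
      comps <- profile$sinusoids[profile$sinusoids$channel == ch, ,
                                 drop = FALSE]
      for (j in seq_len(nrow(comps))) {
        phase <- stats::runif(1L, 0, 2 * pi)
        x <- x + comps$amplitude[j] *
          sin(2 * pi * comps$frequency_hz[j] * t + phase)
      }
    }
    if (profile$noise_sd[[ch]] > 0) {
      sd_b <- profile$noise_sd[[ch]]
      if (profile$noise_jitter > 0)
        sd_b <- sd_b * stats::runif(1L, 1 - profile$noise_jitter,
                                    1 + profile$noise_jitter)
      x <- x + stats::rnorm(n, 0, sd_b)
    }
    if (profile$impulse_rate[[ch]] > 0) {
      n_imp <- stats::rpois(1L, profile$impulse_rate[[ch]] * n / fs)
      if (n_imp > 0) {
        at <- sample.int(n, min(n_imp, n), replace = FALSE)
        sgn <- if (profile$impulse_sign == "random")
          sample(c(-1, 1), length(at), replace = TRUE) else 1
        x[at] <- x[at] + sgn * profile$impulse_amp[[ch]]
      }
    }
    out[, ch] <- x
  }
  out
}

#' Generate a labeled synthetic recording
#'
#' Concatenates `bouts_per_activity` labeled bouts per activity (activities
#' interleaved round-robin), each bout being DC + sinusoids (fresh random
#' phase per bout) + Gaussian noise + Poisson-timed impulses on every
#' channel. Interval labels are exact and the output is bit-reproducible
#' from the configuration seed; the caller's RNG state is left untouched.
#'
#' @param cfg a [sim_config()].
#' @param experiment_id,user_id identifiers stamped on the recording.
#' @return a [labeled_recording()].
#' @export
generate_recording <- function(cfg, experiment_id = 1L, user_id = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$sample_rate_hz
  n_bout <- as.integer(round(cfg$bout_duration_s * fs))
  n_act <- length(cfg$profiles)
  n_total <- n_bout * n_act * cfg$bouts_per_activity
  .with_seed(cfg$seed, {
    sig <- matrix(0, nrow = n_total, ncol = 6L,
                  dimnames = list(NULL, .channel_order))
    iv <- data.frame(activity_id = integer(), start_sample = integer(),
                     end_sample = integer())
    pos <- 0L
    for (b in seq_len(cfg$bouts_per_activity)) {
      for (p in cfg$profiles) {
        sig[pos + seq_len(n_bout), ] <- .simulate_bout(p, n_bout, fs)
        iv <- rbind(iv, data.frame(activity_id = p$activity_id,
                                   start_sample = pos + 1L,
                                   end_sample = pos + n_bout))
        pos <- pos + n_bout
      }
    }
    labeled_recording(sig[, 1:3], sig[, 4:6], iv, sample_rate_hz = fs,
                      experiment_id = experiment_id, user_id = user_id)
  })
}

#' Write recordings in the raw smartphone-dataset text dialect
#'
#' Each recording yields `acc_expNN_userNN.txt` and `gyro_expNN_userNN.txt`
#' (one sample per line, three decimal columns), plus a shared `labels.txt`
#' with five integer columns (experiment, user, activity, start, end).
#'
#' @param recordings a [labeled_recording()] or list of them.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_hapt_dataset <- function(recordings, dir) {
  if (inherits(recordings, "labeled_recording"))
    recordings <- list(recordings)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- NULL
  for (rec in recordings) {
    tag <- sprintf("exp%02d_user%02d", rec$experiment_id, rec$user_id)
    utils::write.table(format(rec$acc, digits = 10, scientific = FALSE,
                              trim = TRUE),
                       file.path(dir, paste0("acc_", tag, ".txt")),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(format(rec$gyro, digits = 10, scientific = FALSE,
                              trim = TRUE),
                       file.path(dir, paste0("gyro_", tag, ".txt")),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    labels <- rbind(labels, data.frame(
      experiment_id = rec$experiment_id, user_id = rec$user_id,
      activity_id = rec$intervals$activity_id,
      start_sample = rec$intervals$start_sample,
      end_sample = rec$intervals$end_sample))
  }
  utils::write.table(labels, file.path(dir, "labels.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a directory written by [write_hapt_dataset()]
#'
#' @param dir dataset directory containing `acc_*`/`gyro_*` files and
#'   `labels.txt`.
#' @param sample_rate_hz sampling rate of the files, default 50.
#' @return list of [labeled_recording()]s, one per experiment/user pair.
#' @export
read_hapt_dataset <- function(dir, sample_rate_hz = 50) {
  labels <- read_labels_file(file.path(dir, "labels.txt"))
  keys <- unique(labels[, c("experiment_id", "user_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    e <- keys$experiment_id[i]
    u <- keys$user_id[i]
    tag <- sprintf("exp%02d_user%02d", e, u)
    sel <- labels$experiment_id == e & labels$user_id == u
    read_raw_recording(
      file.path(dir, paste0("acc_", tag, ".txt")),
      file.path(dir, paste0("gyro_", tag, ".txt")),
      labels[sel, c("activity_id", "start_sample", "end_sample")],
      sample_rate_hz = sample_rate_hz,
      experiment_id = e, user_id = u)
  })
}
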