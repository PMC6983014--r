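# shared fixture builders; everything is generated in code at test time

# a tiny labeled recording with known content
toy_recording <- function(T = 400L, intervals = NULL, seed = 99L) {
  if (is.null(intervals))
    intervals <- data.frame(activity_id = c(1L, 2L),
                            start_sample = c(1L, 201L),
                            end_sample = c(200L, 400L))
  harsel:::.with_seed(seed, {
    acc <- matrix(rnorm(3L * T), ncol = 3L)
    gyro <- matrix(rnorm(3L * T), ncol = 3L)
    labeled_recording(acc, gyro, intervals)
  })
}

# a signal window wrapping a given 6-column matrix
toy_window <- function(channels, label = 1L, fs = 50) {
  channels <- as.matrix(channels)
  colnames(channels) <- c("acc_x", "acc_y", "acc_z",
                          "gyro_x", "gyro_y", "gyro_z")
  structure(list(channels = channels, label = as.integer(label),
                 experiment_id = 1L, user_id = 1L, start_sample = 1L,
                 sample_rate_hz = fs),
            class = "signal_window")
}

random_window <- function(n = 128L, seed = 1L) {
  harsel:::.with_seed(seed, toy_window(matrix(rnorm(n * 6L), ncol = 6L)))
}

# independent naive-loop oracles for the time-domain feature formulas
oracle_time_feature <- function(kind, x, partner = NULL) {
  n <- length(x)
  m <- sum(x) / n
  pop_sd <- sqrt(sum((x - m)^2) / n)
  peak <- max(abs(x))
  am <- sum(abs(x)) / n
  rms <- sqrt(sum(x^2) / n)
  sra <- (sum(sqrt(abs(x))) / n)^2
  switch(kind,
    mean = m,
    std = sqrt(sum((x - m)^2) / (n - 1)),
    median = stats::median(x),
    max = max(x),
    min = min(x),
    iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
    correlation = ,
    cross_correlation = {
      mp <- sum(partner) / n
      sp <- sqrt(sum((partner - mp)^2) / n)
      if (pop_sd == 0 || sp == 0) 0
      else (sum((x - m) * (partner - mp)) / n) / (pop_sd * sp)
    },
    skewness = if (pop_sd == 0) 0 else sum(((x - m) / pop_sd)^3) / n,
    kurtosis = if (pop_sd == 0) 0 else sum(((x - m) / pop_sd)^4) / n,
    abs_mean = am,
    variance = sum((x - m)^2) / n,
    rms = rms,
    energy = sum(abs(x)^2),
    sra = sra,
    ppv = max(x) - min(x),
    crest_factor = if (rms == 0) 0 else peak / rms,
    impulse_factor = if (am == 0) 0 else peak / am,
    margin_factor = if (sra == 0) 0 else peak / sra,
    shape_factor = if (am == 0) 0 else rms / am)
}

# brute-force O(n^2) DFT oracle for the spectral features
oracle_spectral <- function(x, fs) {
  n <- length(x)
  xc <- x - mean(x)
  ks <- seq_len(n %/% 2L)
  P <- vapply(ks, function(k) {
    re <- sum(xc * cos(-2 * pi * k * (0:(n - 1L)) / n))
    im <- sum(xc * sin(-2 * pi * k * (0:(n - 1L)) / n))
    re^2 + im^2
  }, numeric(1L))
  f <- ks * fs / n
  if (sum(P) == 0) return(c(0, 0, 0))
  fc <- sum(f * P) / sum(P)
  c(fc, sqrt(sum(f^2 * P) / sum(P)), sqrt(sum((f - fc)^2 * P) / sum(P)))
}

# brute-force objective: all pairwise loops, exhaustive median search
oracle_objective <- function(x, labels, zscore = TRUE) {
  x <- as.matrix(x)
  if (zscore) {
    for (j in seq_len(ncol(x))) {
      s <- stats::sd(x[, j])
      x[, j] <- (x[, j] - mean(x[, j])) / (if (s > 0) s else 1)
    }
  }
  d <- function(a, b) sqrt(sum((a - b)^2))
  classes <- sort(unique(labels))
  comp <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    pts <- x[labels == classes[ci], , drop = FALSE]
    cum <- numeric(nrow(pts))
    for (i in seq_len(nrow(pts)))
      for (j in seq_len(nrow(pts)))
        cum[i] <- cum[i] + d(pts[i, ], pts[j, ])
    med <- which.min(cum)
    comp[ci] <- max(vapply(seq_len(nrow(pts)),
                           function(i) d(pts[med, ], pts[i, ]), numeric(1L)))
  }
  btw <- Inf
  for (ci in seq_along(classes)) for (cj in seq_along(classes)) {
    if (cj <= ci) next
    a <- x[labels == classes[ci], , drop = FALSE]
    b <- x[labels == classes[cj], , drop = FALSE]
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      btw <- min(btw, d(a[i, ], b[j, ]))
  }
  den <- max(comp)
  if (den > 0) btw / den else if (btw > 0) 1e12 else 0
}

# exhaustive best subset of size <= d_max
oracle_best_subset <- function(n_features, J, d_max) {
  best <- list(J = -Inf, subset = integer(0))
  for (k in seq_len(d_max)) {
    cmb <- utils::combn(n_features, k)
    for (i in seq_len(ncol(cmb))) {
      v <- J(cmb[, i])
      if (v > best$J) best <- list(J = v, subset = cmb[, i])
    }
  }
  best
}

# small labeled gaussian point-set for objective / classifier tests
toy_points <- function(n_per = 10L, centers = list(c(0, 0), c(4, 4), c(8, 0)),
                       sd = 0.5, seed = 5L) {
  harsel:::.with_seed(seed, {
    x <- do.call(rbind, lapply(centers, function(ce)
      cbind(rnorm(n_per, ce[1L], sd), rnorm(n_per, ce[2L], sd))))
    list(x = x, labels = rep(seq_along(centers), each = n_per))
  })
}
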