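# independent reference implementations used to validate the fast paths,
# plus small fixture builders

# minimal signal object for feeding detect_peaks / smooth_trace directly
mk_signal <- function(values, dt = 0.01, t0 = 0, id = "test") {
  structure(list(time = t0 + dt * (seq_along(values) - 1), values = values,
                 sample_rate_hz = 1 / dt, participant_id = id),
            class = "sync_signal")
}

mk_train <- function(times, id = "train", threshold = 2) {
  structure(list(participant_id = id, peak_times = sort(times),
                 peak_amplitudes = rep(threshold + 1, length(times)),
                 threshold = threshold),
            class = "peak_train")
}

mk_pd <- function(diffs_ms, duration_min = 1, window_ms = 1000,
                  dyad_id = "test") {
  structure(list(dyad_id = dyad_id, diffs_ms = diffs_ms,
                 window_ms = window_ms, duration_min = duration_min,
                 n_speaker_peaks = length(diffs_ms),
                 n_listener_peaks = length(diffs_ms)),
            class = "phase_diff_set")
}

mk_trace <- function(ax, ay = ax * 0, az = ax * 0 + 1, dt = 0.01,
                     id = "trace") {
  accel_trace(dt * (seq_along(ax) - 1), ax, ay, az, participant_id = id)
}

# O(n) scan for strict interior local maxima above a threshold
oracle_peaks <- function(values, threshold = 2) {
  idx <- integer(0)
  for (i in seq_along(values)) {
    if (i == 1L || i == length(values)) next
    if (values[i] > values[i - 1] && values[i] > values[i + 1] &&
        values[i] >= threshold)
      idx <- c(idx, i)
  }
  idx
}

# exhaustive one-to-one matcher: enumerate every speaker-listener pair within
# the window, then repeatedly accept the smallest |offset| pair (ties toward
# positive lag, then earlier speaker time) among those with both peaks unused
oracle_match <- function(ts, tl, window_s = 1) {
  pairs <- expand.grid(i = seq_along(ts), j = seq_along(tl))
  pairs$dt <- tl[pairs$j] - ts[pairs$i]
  pairs <- pairs[abs(pairs$dt) <= window_s, , drop = FALSE]
  out <- numeric(0)
  used_s <- logical(length(ts)); used_l <- logical(length(tl))
  while (nrow(pairs)) {
    best <- order(abs(pairs$dt), -sign(pairs$dt), ts[pairs$i])[1]
    i <- pairs$i[best]; j <- pairs$j[best]
    out <- c(out, pairs$dt[best])
    used_s[i] <- TRUE; used_l[j] <- TRUE
    pairs <- pairs[pairs$i != i & pairs$j != j, , drop = FALSE]
  }
  sort(out * 1000)
}

# moment-formula reference for the four features
oracle_features <- function(x, duration_min) {
  n <- length(x)
  m <- sum(x) / n
  s2 <- sum((x - m)^2) / (n - 1)
  g2 <- n * sum((x - m)^4) / sum((x - m)^2)^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  list(density = n / duration_min, mean = m, sd = sqrt(s2), kurtosis = G2)
}

coef_vec <- function(f) {
  c(f$density_per_min, f$mean_ms, f$sd_ms, f$kurtosis)
}

# all-pairs U count with half-credit for ties
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}
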