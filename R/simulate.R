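#' Configuration for a synthetic dyad
#'
#' Parameters of the event-based generative model used to test the pipeline
#' end to end. A speaker produces head nods as a hard-core renewal process
#' (exponential gaps plus a minimum separation of `2 * nod_width_ms`, with
#' the gap rate solved so the mean nod rate equals
#' `speaker_nod_rate_per_min` exactly). Each speaker nod elicits a listener
#' backchannel response with probability `response_prob` at a lag drawn from
#' a normal distribution truncated to +/- 1 s, so every coupled pair stays
#' inside the phase-matching window and recovery targets are exact. The
#' listener additionally nods spontaneously (uncoupled) as a Poisson process.
#' Every event is rendered on the triaxial channels as a raised-cosine pulse
#' of width `nod_width_ms`, dominantly on the vertical axis (which also
#' carries a unit gravity baseline) with small cross-axis leakage; the pulse
#' amplitude is calibrated per trace so the post-normalization smoothed peak
#' height is at least `nod_amplitude_z` SD units (the amplitude is set so
#' pulses dominate the signal variance; an error is raised if the floor is
#' unattainable at the configured event density). White Gaussian sensor
#' noise of per-axis SD `noise_sd` is added.
#'
#' The defaults emulate a typical session between two typically developing
#' adults: nods at 23.3/min, a 41% backchannel response rate at a lag of
#' +90 +/- 300 ms, and a small spontaneous listener rate. See
#' [td_sim_config()] / [asd_sim_config()] for the two study regimes.
#'
#' @param duration_s session length in seconds.
#' @param sample_rate_hz sampling rate; nominal 100.
#' @param speaker_nod_rate_per_min mean speaker nod rate.
#' @param response_prob probability a speaker nod elicits a response.
#' @param response_lag_mean_ms,response_lag_sd_ms response latency
#'   distribution (truncated to +/- 1000 ms).
#' @param spontaneous_listener_rate_per_min rate of uncoupled listener nods.
#' @param nod_amplitude_z target peak height in SD units; must exceed the
#'   detection threshold of 2.
#' @param nod_width_ms raised-cosine pulse width.
#' @param noise_sd per-axis white-noise SD (sensor units).
#' @param seed integer seed; identical seeds give identical output.
#' @return A `dyad_sim_config` list.
#' @export
dyad_sim_config <- function(duration_s = 600, sample_rate_hz = 100,
                            speaker_nod_rate_per_min = 23.3,
                            response_prob = 0.41,
                            response_lag_mean_ms = 90,
                            response_lag_sd_ms = 300,
                            spontaneous_listener_rate_per_min = 0.5,
                            nod_amplitude_z = 3.0,
                            nod_width_ms = 400,
                            noise_sd = 0.05,
                            seed = NULL) {
  cfg <- list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
              speaker_nod_rate_per_min = speaker_nod_rate_per_min,
              response_prob = response_prob,
              response_lag_mean_ms = response_lag_mean_ms,
              response_lag_sd_ms = response_lag_sd_ms,
              spontaneous_listener_rate_per_min =
                spontaneous_listener_rate_per_min,
              nod_amplitude_z = nod_amplitude_z,
              nod_width_ms = nod_width_ms, noise_sd = noise_sd, seed = seed)
  with(cfg, {
    stopifnot(duration_s > 0, sample_rate_hz > 0,
              speaker_nod_rate_per_min >= 0,
              response_prob >= 0, response_prob <= 1,
              response_lag_sd_ms > 0, spontaneous_listener_rate_per_min >= 0,
              nod_amplitude_z > 2, nod_width_ms > 0, noise_sd > 0)
  })
  min_sep <- 2 * cfg$nod_width_ms / 1000
  if (cfg$speaker_nod_rate_per_min / 60 >= 1 / min_sep)
    stop("event density too high for the minimum-separation constraint (",
         "rate must be below ", round(60 / min_sep, 1), "/min at width ",
         cfg$nod_width_ms, " ms)", call. = FALSE)
  structure(cfg, class = "dyad_sim_config")
}

#' Study-regime presets for the simulator
#'
#' `td_sim_config()` is the tightly coupled regime: frequent responses with
#' a peaked lag distribution around +90 ms. `asd_sim_config()` is the
#' loosely coupled regime: the same speaker behaviour but roughly half the
#' response probability, a much wider lag jitter, and more uncoupled
#' spontaneous listener nods, producing the flat, long-tailed lag
#' distribution with lower event density.
#'
#' @param ... overrides passed to [dyad_sim_config()].
#' @return A `dyad_sim_config`.
#' @export
td_sim_config <- function(...) {
  do.call(dyad_sim_config, modifyList(
    list(response_prob = 0.41, response_lag_mean_ms = 90,
         response_lag_sd_ms = 300, spontaneous_listener_rate_per_min = 0.5),
    list(...)))
}

#' @rdname td_sim_config
#' @export
asd_sim_config <- function(...) {
  do.call(dyad_sim_config, modifyList(
    list(response_prob = 0.20, response_lag_mean_ms = 90,
         response_lag_sd_ms = 450, spontaneous_listener_rate_per_min = 1.5),
    list(...)))
}

# hard-core renewal event times on [margin, duration - margin]:
# gaps are min_sep + Exp(lambda'), lambda' solved so the mean gap is 1/rate
hardcore_events <- function(rate_per_s, duration_s, min_sep_s, margin_s) {
  if (rate_per_s <= 0) return(numeric(0))
  mean_gap <- 1 / rate_per_s
  if (mean_gap <= min_sep_s)
    stop("event density too high for separation constraint", call. = FALSE)
  lambda <- 1 / (mean_gap - min_sep_s)
  hi <- duration_s - margin_s
  # expected count + slack, then trim
  n_draw <- max(16L, ceiling(duration_s * rate_per_s * 1.5 + 10))
  t <- margin_s + runif(1) * mean_gap +
    cumsum(c(0, min_sep_s + rexp(n_draw - 1L, lambda)))
  while (t[length(t)] < hi) {
    t <- c(t, t[length(t)] + cumsum(min_sep_s + rexp(n_draw, lambda)))
  }
  t[t <= hi]
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# render events as raised-cosine pulses on a triaxial grid; amplitude is
# calibrated so the z-scored, smoothed peak height is at least target_z
render_trace <- function(events_s, cfg, participant_id, target_z,
                         smooth_samples = 11L) {
  dt <- 1 / cfg$sample_rate_hz
  n <- round(cfg$duration_s / dt) + 1L
  tgrid <- seq(0, by = dt, length.out = n)
  w <- cfg$nod_width_ms / 1000
  u <- numeric(n)
  half <- w / 2
  for (ev in events_s) {
    i0 <- max(1L, ceiling((ev - half) / dt) + 1L)
    i1 <- min(n, floor((ev + half) / dt) + 1L)
    if (i1 >= i0) {
      tt <- tgrid[i0:i1] - ev
      u[i0:i1] <- u[i0:i1] + 0.5 * (1 + cos(pi * tt / half))
    }
  }
  # Amplitude calibration. In a z-scored sparse-pulse signal the peak height
  # in SD units is bounded above by the pulse geometry alone
  # (z_max = (peak - mean) / sd of the pulse train); noise only lowers it.
  # The raw amplitude is therefore chosen so the pulses dominate the signal
  # variance (pulse-to-noise variance ratio 50, i.e. relative noise ~0.14 SD
  # and ~0.04 SD after the 100 ms smoothing, so each pulse yields exactly one
  # smoothed peak), and target_z acts as a guaranteed floor on the realized
  # smoothed peak height.
  if (length(events_s)) {
    shape <- 0.5 * (1 + cos(pi * seq(-half, half, by = dt) / half))
    sm <- stats::filter(shape, rep(1 / smooth_samples, smooth_samples),
                        sides = 1)
    us_max <- max(sm, na.rm = TRUE)
    u_bar <- mean(u)
    var_u <- mean((u - u_bar)^2)
    A <- sqrt(50 / var_u) * cfg$noise_sd
    realized_z <- A * (us_max - u_bar) / sqrt(A^2 * var_u + cfg$noise_sd^2)
    if (realized_z < target_z)
      stop(sprintf(paste0(
        "nod_amplitude_z = %.2f unattainable at this event density ",
        "(geometric ceiling %.2f SD)"), target_z, realized_z), call. = FALSE)
  } else {
    A <- 0
  }
  ax <- 0.25 * A * u + rnorm(n, 0, cfg$noise_sd)
  ay <- 0.15 * A * u + rnorm(n, 0, cfg$noise_sd)
  az <- 1 + A * u + rnorm(n, 0, cfg$noise_sd)     # gravity baseline on z
  accel_trace(tgrid, ax, ay, az, participant_id = participant_id,
              sample_rate_hz = cfg$sample_rate_hz)
}

#' Simulate one synthetic dyad with ground truth
#'
#' Draws speaker and listener event trains from the generative model of
#' [dyad_sim_config()], renders both as triaxial accelerometer traces, and
#' returns the event-level ground truth (which listener nods were responses
#' to which speaker nods, and at what true lag) so detector recall and lag
#' recovery can be scored exactly.
#'
#' @param cfg a [dyad_sim_config()].
#' @param dyad_id label for the dyad.
#' @return A `dyad_sim` list: `speaker`, `listener` ([accel_trace()]s),
#'   `truth` (list with `speaker_event_times`, `listener_event_times`,
#'   `coupled_pairs` data frame of `speaker_time`, `listener_time`,
#'   `true_lag_ms`), and `config`.
#' @export
simulate_dyad <- function(cfg, dyad_id = "sim") {
  stopifnot(inherits(cfg, "dyad_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  w <- cfg$nod_width_ms / 1000
  margin <- w / 2 + 1.1        # room for a +/- 1 s response near the edges
  sp <- hardcore_events(cfg$speaker_nod_rate_per_min / 60, cfg$duration_s,
                        2 * w, margin)
  responded <- runif(length(sp)) < cfg$response_prob
  lags_ms <- rnorm_trunc(sum(responded), cfg$response_lag_mean_ms,
                         cfg$response_lag_sd_ms, -1000, 1000)
  resp_t <- sp[responded] + lags_ms / 1000
  # enforce the pulse-separation invariant among responses
  keep <- !logical(length(resp_t))
  ord <- order(resp_t)
  last <- -Inf
  for (k in ord) {
    if (resp_t[k] - last >= w) last <- resp_t[k] else keep[k] <- FALSE
  }
  # spontaneous (uncoupled) listener nods: Poisson, kept only when clear of
  # every retained event by at least the pulse width
  n_spont <- stats::rpois(1, cfg$spontaneous_listener_rate_per_min / 60 *
                            cfg$duration_s)
  spont <- sort(runif(n_spont, margin, cfg$duration_s - margin))
  li <- sort(resp_t[keep])
  spont_keep <- vapply(spont, function(s) {
    all(abs(li - s) >= w) }, logical(1))
  if (length(spont)) {
    sk <- spont[spont_keep]
    # also enforce separation among the spontaneous nods themselves
    if (length(sk) > 1L) sk <- sk[c(TRUE, diff(sk) >= w)]
    listener_events <- sort(c(li, sk))
  } else listener_events <- li
  ok_sp <- sp[responded][keep]
  ok_li <- resp_t[keep]
  o <- order(ok_li)
  truth <- list(
    speaker_event_times = sp,
    listener_event_times = listener_events,
    coupled_pairs = data.frame(speaker_time = ok_sp[o],
                               listener_time = ok_li[o],
                               true_lag_ms = (ok_li[o] - ok_sp[o]) * 1000))
  structure(
    list(speaker = render_trace(sp, cfg, paste0(dyad_id, "_speaker"),
                                cfg$nod_amplitude_z),
         listener = render_trace(listener_events, cfg,
                                 paste0(dyad_id, "_listener"),
                                 cfg$nod_amplitude_z),
         truth = truth, config = cfg, dyad_id = dyad_id),
    class = "dyad_sim")
}

#' @export
print.dyad_sim <- function(x, ...) {
  cat(sprintf("<dyad_sim> %s: %.0f s, %d speaker nods, %d listener nods (%d coupled)\n",
              x$dyad_id, x$config$duration_s,
              length(x$truth$speaker_event_times),
              length(x$truth$listener_event_times),
              nrow(x$truth$coupled_pairs)))
  invisible(x)
}

#' Simulate a two-group dyad study
#'
#' Generates `n_dyads_per_group` dyads under each of two regimes (mirroring
#' an 18 + 18 TD vs ASD design), with per-dyad seeds derived
#' deterministically from `seed`. With `out_dir` set, writes one CSV pair
#' per dyad, a YAML manifest in the format [read_manifest()] accepts, and a
#' JSON ground-truth sidecar; with `out_dir = NULL` the dyads are returned
#' in memory.
#'
#' @param cfg_td,cfg_asd [dyad_sim_config()]s for the two regimes (their
#'   `seed` fields are overridden by the derived per-dyad seeds).
#' @param n_dyads_per_group dyads per group, `>= 2`.
#' @param seed master integer seed.
#' @param out_dir output directory, or `NULL` for an in-memory corpus.
#' @return Invisibly (visibly when `out_dir = NULL`) a list with `dyads`
#'   (list of `dyad_sim`), `groups` (character vector), `dyad_ids`, and —
#'   when written — `manifest_path`.
#' @export
simulate_group_study <- function(cfg_td, cfg_asd, n_dyads_per_group = 18L,
                                 seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cfg_td, "dyad_sim_config"),
            inherits(cfg_asd, "dyad_sim_config"), n_dyads_per_group >= 2)
  n <- as.integer(n_dyads_per_group)
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 2L * n)
  ids <- c(sprintf("TD%02d", seq_len(n)), sprintf("ASD%02d", seq_len(n)))
  groups <- rep(c("TD", "ASD"), each = n)
  dyads <- lapply(seq_len(2L * n), function(i) {
    cfg <- if (groups[i] == "TD") cfg_td else cfg_asd
    cfg$seed <- seeds[i]
    simulate_dyad(cfg, dyad_id = ids[i])
  })
  out <- list(dyads = dyads, groups = groups, dyad_ids = ids)
  if (is.null(out_dir)) return(out)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    sf <- paste0(ids[i], "_speaker.csv")
    lf <- paste0(ids[i], "_listener.csv")
    write_trace(dyads[[i]]$speaker, file.path(out_dir, sf))
    write_trace(dyads[[i]]$listener, file.path(out_dir, lf))
    cfg <- dyads[[i]]$config
    sessions[[i]] <- list(dyad_id = ids[i], group = groups[i],
                          speaker_file = sf, listener_file = lf,
                          start_time_s = 0, end_time_s = cfg$duration_s)
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(sessions = sessions), manifest_path)
  truth <- lapply(dyads, function(d) list(
    dyad_id = d$dyad_id,
    speaker_event_times = d$truth$speaker_event_times,
    listener_event_times = d$truth$listener_event_times,
    coupled_pairs = d$truth$coupled_pairs))
  names(truth) <- ids
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  out$manifest_path <- manifest_path
  invisible(out)
}
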