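#' Fit the phase-difference synchrony model to one dyad
#'
#' Runs the full per-dyad pipeline on a speaker and a listener trace:
#' magnitude, z-score normalization over the active window, 100 ms
#' moving-average smoothing, amplitude-thresholded peak detection, and
#' one-to-one nearest-peak matching within the phase window. The result
#' bundles the detected peak trains, the signed phase differences and the
#' four synchrony features.
#'
#' @param speaker,listener [accel_trace()] objects, or file paths readable
#'   by [read_trace()].
#' @param window optional numeric `c(start_s, end_s)` active recording
#'   window (the synchronization claps); both traces are trimmed to it with
#'   [trim_to_window()]. When omitted, the overlap of the two traces'
#'   supports is used.
#' @param threshold peak amplitude threshold in SD units; default 2.0.
#' @param match_window_s phase-matching half-window in seconds; default 1.0.
#' @param smooth_samples moving-average length in samples; default 11
#'   (100 ms at 100 Hz).
#' @param matching `"one_to_one"` (default) or `"many_to_one"`; see
#'   [match_peaks()].
#' @param kurtosis kurtosis variant, see [compute_features()].
#' @param max_missing_fraction missing-data exclusion threshold applied to
#'   both traces; default 0.05.
#' @param dyad_id label for the dyad; defaults to
#'   `"<speaker_id>-<listener_id>"`.
#' @param centered anchor the smoothing window at its center instead of its
#'   start (both traces receive the same convention, so lags are unchanged).
#'
#' @return An object of class `dyad_synchrony` with components
#'   `features` (a `sync_features`), `phase_diffs` (a `phase_diff_set`),
#'   `speaker_peaks`, `listener_peaks` (`peak_train`s), `window`,
#'   `duration_min`, and `control` (the resolved parameters).
#'
#' @examples
#' cfg <- dyad_sim_config(duration_s = 120, seed = 7)
#' sim <- simulate_dyad(cfg)
#' fit <- dyad_synchrony(sim$speaker, sim$listener)
#' coef(fit)
#' summary(fit)
#' @export
dyad_synchrony <- function(speaker, listener, window = NULL,
                           threshold = 2.0, match_window_s = 1.0,
                           smooth_samples = 11L,
                           matching = c("one_to_one", "many_to_one"),
                           kurtosis = c("excess", "raw", "population"),
                           max_missing_fraction = 0.05,
                           dyad_id = NULL, centered = FALSE) {
  matching <- match.arg(matching)
  kurtosis <- match.arg(kurtosis)
  if (is.character(speaker)) speaker <- read_trace(speaker)
  if (is.character(listener)) listener <- read_trace(listener)
  stopifnot(inherits(speaker, "accel_trace"), inherits(listener, "accel_trace"))
  if (is.null(window)) {
    window <- c(max(speaker$time[1], listener$time[1]),
                min(speaker$time[length(speaker$time)],
                    listener$time[length(listener$time)]) +
                  1 / min(speaker$sample_rate_hz, listener$sample_rate_hz))
  }
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be c(start_s, end_s) with end > start", call. = FALSE)
  dyad_id <- dyad_id %||% paste(speaker$participant_id,
                                listener$participant_id, sep = "-")
  prep <- function(tr) {
    tr <- trim_to_window(tr, window[1], window[2])
    tr <- check_missing(tr, max_missing_fraction)
    sm <- smooth_trace(zscore(magnitude(tr)), smooth_samples,
                       centered = centered)
    detect_peaks(sm, threshold)
  }
  sp <- prep(speaker)
  lp <- prep(listener)
  duration_min <- (window[2] - window[1]) / 60
  pd <- match_peaks(sp, lp, window_s = match_window_s, matching = matching,
                    dyad_id = dyad_id, duration_min = duration_min)
  feats <- compute_features(pd, kurtosis = kurtosis)
  structure(
    list(features = feats, phase_diffs = pd,
         speaker_peaks = sp, listener_peaks = lp,
         window = window, duration_min = duration_min, dyad_id = dyad_id,
         control = list(threshold = threshold,
                        match_window_s = match_window_s,
                        smooth_samples = as.integer(smooth_samples),
                        matching = matching, kurtosis = kurtosis,
                        centered = centered,
                        max_missing_fraction = max_missing_fraction)),
    class = "dyad_synchrony")
}

#' @export
print.dyad_synchrony <- function(x, ...) {
  f <- x$features
  cat(sprintf("Dyad synchrony fit: %s (%.2f min)\n", x$dyad_id,
              x$duration_min))
  cat(sprintf("  speaker peaks: %d   listener peaks: %d   matched events: %d\n",
              length(x$speaker_peaks), length(x$listener_peaks), f$n_events))
  cat(sprintf("  density %.2f /min, mean %.1f ms, sd %.1f ms, kurtosis %.3f\n",
              f$density_per_min, f$mean_ms, f$sd_ms, f$kurtosis))
  invisible(x)
}

#' @export
coef.dyad_synchrony <- function(object, ...) {
  f <- object$features
  c(density = f$density_per_min, mean_ms = f$mean_ms, sd_ms = f$sd_ms,
    kurtosis = f$kurtosis)
}

#' @export
summary.dyad_synchrony <- function(object, halfwidth_ms = 300, ...) {
  pd <- object$phase_diffs
  out <- list(fit = object,
              central_mass = if (length(pd$diffs_ms))
                central_mass(pd, halfwidth_ms) else NA_real_,
              halfwidth_ms = halfwidth_ms,
              speaker_density = length(object$speaker_peaks) /
                object$duration_min,
              listener_density = length(object$listener_peaks) /
                object$duration_min)
  class(out) <- "summary.dyad_synchrony"
  out
}

#' @export
print.summary.dyad_synchrony <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  speaker nod density %.2f /min, listener %.2f /min\n",
              x$speaker_density, x$listener_density))
  cat(sprintf("  %.1f%% of events within +/- %g ms of the mean lag\n",
              100 * x$central_mass, x$halfwidth_ms))
  invisible(x)
}

#' Plot the phase-difference histogram of a fitted dyad
#'
#' Draws the 100 ms-binned relative-frequency histogram of the signed lags,
#' with the mean lag marked.
#'
#' @param x a `dyad_synchrony` fit.
#' @param bin_ms bin width in ms.
#' @param ... passed to [graphics::barplot()].
#' @return The `phase_histogram`, invisibly.
#' @export
plot.dyad_synchrony <- function(x, bin_ms = 100, ...) {
  h <- phase_histogram(x$phase_diffs, bin_ms)
  mids <- (h$bin_left_ms + h$bin_right_ms) / 2
  bp <- barplot(h$rel_freq, space = 0, col = "grey80", border = "grey40",
                ylab = "relative frequency",
                xlab = "phase difference (ms), listener - speaker",
                main = x$dyad_id, ...)
  sel <- seq(1, length(mids), by = max(1L, length(mids) %/% 10L))
  axis(1, at = bp[sel], labels = mids[sel])
  if (!h$empty) {
    m <- mean(x$phase_diffs$diffs_ms)
    abline(v = bp[1] - 0.5 + (m + x$phase_diffs$window_ms) /
             (h$bin_right_ms[1] - h$bin_left_ms[1]), col = "red", lwd = 2)
  }
  invisible(h)
}

#' Simulate synthetic dyads resembling a fitted one
#'
#' Maps the fitted synchrony features back onto generator parameters — the
#' observed speaker nod density becomes the nod rate, the matched-event
#' density divided by it the response probability, and the lag mean/SD the
#' response-latency distribution — and draws `nsim` fresh synthetic dyads
#' from [simulate_dyad()]. Useful for parametric-bootstrap style checks of
#' the pipeline on data that looks like the fitted session.
#'
#' @param object a `dyad_synchrony` fit with at least 2 matched events.
#' @param nsim number of synthetic dyads.
#' @param seed integer seed for reproducibility.
#' @param ... overrides passed to [dyad_sim_config()].
#' @return A list of `nsim` results from [simulate_dyad()].
#' @export
simulate.dyad_synchrony <- function(object, nsim = 1, seed = NULL, ...) {
  f <- object$features
  if (f$n_events < 2L)
    stop("too few matched events to calibrate a simulator", call. = FALSE)
  sp_rate <- length(object$speaker_peaks) / object$duration_min
  base <- list(duration_s = object$window[2] - object$window[1],
               speaker_nod_rate_per_min = sp_rate,
               response_prob = min(1, f$density_per_min / sp_rate),
               response_lag_mean_ms = f$mean_ms,
               response_lag_sd_ms = f$sd_ms,
               spontaneous_listener_rate_per_min = 0)
  over <- list(...)
  base[names(over)] <- over
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  lapply(seq_len(nsim), function(i) {
    cfg <- do.call(dyad_sim_config, c(base, list(seed = seeds[i])))
    simulate_dyad(cfg)
  })
}
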