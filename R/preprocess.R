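#' Euclidean magnitude of a triaxial trace
#'
#' Collapses the three axes to a single nonnegative movement-intensity signal,
#' `sqrt(ax^2 + ay^2 + az^2)` per sample. This is the first step of the
#' phase-difference pipeline: head nods and speech-related oscillations show
#' up as magnitude bursts regardless of their orientation.
#'
#' @param trace an [accel_trace()].
#' @return A `magnitude_trace`: list with `time`, `values`,
#'   `sample_rate_hz`, `participant_id`.
#' @export
magnitude <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  structure(
    list(time = trace$time,
         values = sqrt(trace$ax^2 + trace$ay^2 + trace$az^2),
         sample_rate_hz = trace$sample_rate_hz,
         participant_id = trace$participant_id,
         window = c(attr(trace, "window_start"), attr(trace, "window_end"))),
    class = c("magnitude_trace", "sync_signal"))
}

#' Z-score normalization of a magnitude trace
#'
#' Centers and scales the magnitude by its mean and sample standard deviation
#' (denominator `T - 1`) computed over the entire trimmed recording. This
#' removes individual differences in movement amplitude (head size, speaking
#' style, sensor units), so two participants' signals become directly
#' comparable: downstream peak detection uses a fixed threshold in SD units.
#'
#' @param mag a `magnitude_trace` from [magnitude()] (any `sync_signal`
#'   works).
#' @return A `normalized_trace`: list with `time`, `values` (mean 0, SD 1),
#'   `source_mean`, `source_sd`, plus carried metadata.
#' @export
zscore <- function(mag) {
  stopifnot(inherits(mag, "sync_signal"))
  v <- mag$values
  if (sum(!is.na(v)) < 2L)
    stop("z-scoring needs at least 2 samples", call. = FALSE)
  m <- mean(v, na.rm = TRUE)
  s <- sd(v, na.rm = TRUE)          # sample SD, divisor T - 1
  if (!is.finite(s) || s == 0)
    stop("degenerate signal: zero variance, cannot z-score", call. = FALSE)
  structure(
    list(time = mag$time, values = (v - m) / s,
         source_mean = m, source_sd = s,
         sample_rate_hz = mag$sample_rate_hz,
         participant_id = mag$participant_id,
         window = mag$window),
    class = c("normalized_trace", "sync_signal"))
}

#' Moving-average smoothing
#'
#' Smooths the normalized magnitude with a forward (causal) moving average of
#' `window_samples` consecutive samples: output `i` is the mean of inputs
#' `i .. i + window_samples - 1`, timestamped at sample `i`. At the nominal
#' 100 Hz the default 11 samples span 100 ms between the first and last
#' sample of the window. Trailing samples with incomplete windows are
#' dropped, so the output is shorter by `window_samples - 1`. The same shift
#' applies to both members of a dyad, so pairwise phase differences are
#' unaffected; `centered = TRUE` anchors the timestamp at the window middle
#' instead (an odd `window_samples` keeps it on-grid).
#'
#' @param norm a `normalized_trace` from [zscore()] (any `sync_signal`).
#' @param window_samples positive integer window length; default 11.
#' @param centered logical; anchor timestamps at the window center.
#' @return A `smoothed_trace`: list with `time`, `values`, `window_samples`,
#'   plus carried metadata.
#' @export
smooth_trace <- function(norm, window_samples = 11L, centered = FALSE) {
  stopifnot(inherits(norm, "sync_signal"))
  w <- as.integer(window_samples)
  if (w < 1L) stop("window_samples must be >= 1", call. = FALSE)
  n <- length(norm$values)
  if (n < w)
    stop("trace shorter than the smoothing window (", n, " < ", w, ")",
         call. = FALSE)
  cs <- cumsum(c(0, norm$values))
  vals <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  anchor <- if (centered) seq_len(n - w + 1L) + (w - 1L) %/% 2L
            else seq_len(n - w + 1L)
  structure(
    list(time = norm$time[anchor], values = vals, window_samples = w,
         sample_rate_hz = norm$sample_rate_hz,
         participant_id = norm$participant_id,
         window = norm$window),
    class = c("smoothed_trace", "sync_signal"))
}

#' @export
print.sync_signal <- function(x, ...) {
  cat(sprintf("<%s> %s: %d samples, %.2f-%.2f s, range [%.3g, %.3g]\n",
              class(x)[1], x$participant_id %||% "?", length(x$values),
              x$time[1], x$time[length(x$time)],
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.sync_signal <- function(x, ...) {
  data.frame(time = x$time, value = x$values)
}
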