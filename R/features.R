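#' Distribution-based synchrony features
#'
#' Summarizes a dyad's phase-difference distribution with four features:
#'
#' * **density** (synchrony activity): matched events per minute of the
#'   analyzed window — how often the pair synchronizes at all;
#' * **mean** (synchrony directionality): mean signed lag in ms — positive
#'   when the listener habitually follows the speaker;
#' * **sd** (synchrony variability): sample SD (divisor `n - 1`) of the lags
#'   in ms — the temporal precision of the coordination;
#' * **kurtosis** (synchrony coherence): kurtosis of the lag distribution —
#'   how strongly events concentrate around the central lag. The default is
#'   sample excess kurtosis with the standard small-sample bias correction
#'   (normal distribution -> 0); `kurtosis = "raw"` gives the uncorrected
#'   moment ratio (normal -> 3) and `"population"` the uncorrected excess.
#'
#' Features that need more events than are available are reported as `NA`
#' rather than 0: the mean needs 1 event, the SD 2, and kurtosis 4 (the bias
#' correction divides by `(n - 2)(n - 3)`). A zero-variance lag set also
#' leaves kurtosis undefined.
#'
#' @param pd a `phase_diff_set` from [match_peaks()] with a positive
#'   `duration_min` (pass `duration_min` here to override).
#' @param kurtosis `"excess"` (default), `"raw"` or `"population"`.
#' @param duration_min optional override of the analyzed duration.
#' @return A `sync_features`: list with `dyad_id`, `n_events`,
#'   `density_per_min`, `mean_ms`, `sd_ms`, `kurtosis`, `kurtosis_mode`.
#' @export
compute_features <- function(pd, kurtosis = c("excess", "raw", "population"),
                             duration_min = NULL) {
  stopifnot(inherits(pd, "phase_diff_set"))
  kurtosis <- match.arg(kurtosis)
  dur <- duration_min %||% pd$duration_min
  if (is.null(dur) || !is.finite(dur) || dur <= 0)
    stop("duration_min must be a positive number of minutes", call. = FALSE)
  x <- pd$diffs_ms
  n <- length(x)
  structure(
    list(dyad_id = pd$dyad_id,
         n_events = n,
         density_per_min = n / dur,
         mean_ms = if (n >= 1L) mean(x) else NA_real_,
         sd_ms = if (n >= 2L) sd(x) else NA_real_,
         kurtosis = sample_kurtosis(x, type = kurtosis),
         kurtosis_mode = kurtosis,
         duration_min = dur),
    class = "sync_features")
}

#' Sample kurtosis of a numeric vector
#'
#' @param x numeric vector.
#' @param type `"excess"` for the bias-corrected sample excess kurtosis
#'   `G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3))` (normal -> 0), `"raw"` for
#'   the plain moment ratio `b2 = n * sum((x-m)^4) / sum((x-m)^2)^2`
#'   (normal -> 3), `"population"` for `g2 = b2 - 3`.
#' @return The kurtosis, or `NA` when `x` is too short (`n < 4` for
#'   `"excess"`, `n < 2` otherwise) or has zero variance.
#' @export
sample_kurtosis <- function(x, type = c("excess", "raw", "population")) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  n <- length(x)
  min_n <- if (type == "excess") 4L else 2L
  if (n < min_n) return(NA_real_)
  d <- x - mean(x)
  s2 <- sum(d^2)
  if (s2 == 0) return(NA_real_)
  b2 <- n * sum(d^4) / s2^2
  switch(type,
         raw = b2,
         population = b2 - 3,
         excess = ((n + 1) * (b2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3)))
}

#' @export
print.sync_features <- function(x, ...) {
  cat(sprintf("<sync_features> %s: %d events over %.2f min\n", x$dyad_id,
              x$n_events, x$duration_min))
  cat(sprintf("  density  %8.3f events/min\n", x$density_per_min))
  cat(sprintf("  mean     %8.2f ms\n", x$mean_ms))
  cat(sprintf("  sd       %8.2f ms\n", x$sd_ms))
  cat(sprintf("  kurtosis %8.3f (%s)\n", x$kurtosis, x$kurtosis_mode))
  invisible(x)
}

#' @export
as.data.frame.sync_features <- function(x, ...) {
  data.frame(dyad_id = x$dyad_id, n_events = x$n_events,
             density = x$density_per_min, mean_ms = x$mean_ms,
             sd_ms = x$sd_ms, kurtosis = x$kurtosis)
}
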