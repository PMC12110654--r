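#' Detect communicative movement peaks
#'
#' A sample is a peak when it is strictly greater than both of its immediate
#' neighbours and its smoothed, normalized amplitude is at least `threshold`
#' (default 2.0, i.e. two standard deviations above the participant's mean
#' movement intensity). The strict local-maximum rule means plateaus are not
#' peaks and the first and last samples never qualify. No refractory period
#' is imposed: the 100 ms smoothing window already separates genuine nods.
#'
#' @param sm a `smoothed_trace` from [smooth_trace()] (any `sync_signal`
#'   with at least 3 samples).
#' @param threshold amplitude threshold in SD units; comparison is `>=`.
#' @return A `peak_train`: list with `participant_id`, `peak_times`
#'   (strictly increasing, seconds), `peak_amplitudes`, `threshold`. May be
#'   empty.
#' @export
detect_peaks <- function(sm, threshold = 2.0) {
  stopifnot(inherits(sm, "sync_signal"))
  v <- sm$values
  n <- length(v)
  if (n < 3L) stop("peak detection needs at least 3 samples", call. = FALSE)
  i <- 2:(n - 1L)
  is_peak <- v[i] > v[i - 1L] & v[i] > v[i + 1L] & v[i] >= threshold
  is_peak[is.na(is_peak)] <- FALSE
  idx <- i[is_peak]
  structure(
    list(participant_id = sm$participant_id,
         peak_times = sm$time[idx],
         peak_amplitudes = v[idx],
         threshold = threshold),
    class = "peak_train")
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train> %s: %d peaks >= %.2f", x$participant_id %||% "?",
              length(x$peak_times), x$threshold))
  if (length(x$peak_times))
    cat(sprintf(" over %.1f s", diff(range(x$peak_times))))
  cat("\n")
  invisible(x)
}

#' @export
length.peak_train <- function(x) length(x$peak_times)

#' @export
as.data.frame.peak_train <- function(x, ...) {
  data.frame(time_s = x$peak_times, amplitude = x$peak_amplitudes)
}

#' Write a peak train as two-column CSV
#'
#' @param peaks a `peak_train`.
#' @param path output path; columns `time_s, amplitude`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_train"))
  write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}
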