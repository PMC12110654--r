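#' Pair speaker and listener peaks into phase differences
#'
#' For every speaker peak the nearest listener peak in time is sought; a pair
#' within `window_s` (default +/- 1.0 s) contributes one synchrony event with
#' signed lag `listener time - speaker time` in milliseconds, so positive
#' lags mean the listener follows the speaker (the backchannel pattern).
#'
#' With the default `matching = "one_to_one"` a listener peak can be claimed
#' by at most one speaker peak: all candidate pairs within the window are
#' ranked by ascending absolute offset and accepted greedily, so a single
#' listener nod cannot inflate the event count against several speaker
#' peaks. Exact ties between a preceding and a following candidate break
#' toward positive lag (listener-follows). `matching = "many_to_one"` is the
#' permissive reading: each speaker peak simply takes its nearest listener
#' peak, reuse allowed.
#'
#' @param speaker,listener `peak_train` objects from [detect_peaks()].
#' @param window_s maximum absolute offset in seconds; default 1.0.
#' @param matching `"one_to_one"` (default) or `"many_to_one"`.
#' @param dyad_id label stored on the result.
#' @param duration_min analyzed duration in minutes (the trimmed window
#'   length); needed downstream for the density feature.
#' @return A `phase_diff_set`: list with `dyad_id`, `diffs_ms` (signed lags,
#'   ms, all within `window_s * 1000`), `window_ms`, `duration_min`,
#'   `n_speaker_peaks`, `n_listener_peaks`.
#' @export
match_peaks <- function(speaker, listener, window_s = 1.0,
                        matching = c("one_to_one", "many_to_one"),
                        dyad_id = "dyad", duration_min = NULL) {
  stopifnot(inherits(speaker, "peak_train"), inherits(listener, "peak_train"))
  matching <- match.arg(matching)
  ts <- speaker$peak_times
  tl <- listener$peak_times
  diffs <- numeric(0)
  if (length(ts) && length(tl)) {
    if (matching == "many_to_one") {
      # nearest listener peak per speaker peak, ties toward positive lag
      lo <- findInterval(ts, tl)                 # last listener peak <= ts
      hi <- pmin(lo + 1L, length(tl))
      lo <- pmax(lo, 1L)
      d_lo <- tl[lo] - ts
      d_hi <- tl[hi] - ts
      pick <- ifelse(abs(d_hi) <= abs(d_lo), d_hi, d_lo)
      diffs <- pick[abs(pick) <= window_s + 1e-12]
    } else {
      # all candidate pairs within the window, greedy by ascending |offset|
      first <- findInterval(ts - window_s, tl, left.open = TRUE) + 1L
      last <- findInterval(ts + window_s, tl)
      keep <- first <= last
      if (any(keep)) {
        si <- rep.int(which(keep), (last - first + 1L)[keep])
        li <- unlist(lapply(which(keep), function(i) first[i]:last[i]),
                     use.names = FALSE)
        dt <- tl[li] - ts[si]
        ord <- order(abs(dt), -sign(dt), ts[si])
        used_s <- logical(length(ts)); used_l <- logical(length(tl))
        res <- numeric(min(length(ts), length(tl))); k <- 0L
        for (p in ord) {
          i <- si[p]; j <- li[p]
          if (!used_s[i] && !used_l[j]) {
            used_s[i] <- TRUE; used_l[j] <- TRUE
            k <- k + 1L; res[k] <- dt[p]
          }
        }
        diffs <- res[seq_len(k)]
      }
    }
  }
  structure(
    list(dyad_id = dyad_id, diffs_ms = as.numeric(diffs) * 1000,
         window_ms = window_s * 1000, duration_min = duration_min,
         n_speaker_peaks = length(ts), n_listener_peaks = length(tl)),
    class = "phase_diff_set")
}

#' @export
print.phase_diff_set <- function(x, ...) {
  cat(sprintf("<phase_diff_set> %s: %d events within +/- %g ms", x$dyad_id,
              length(x$diffs_ms), x$window_ms))
  if (length(x$diffs_ms))
    cat(sprintf(", mean %.1f ms", mean(x$diffs_ms)))
  cat("\n")
  invisible(x)
}

#' Binned phase-difference distribution
#'
#' Bins the signed lags into left-closed, right-open 100 ms bins spanning
#' the matching window (the final bin is closed so the right edge is
#' included), and normalizes counts to relative frequencies.
#'
#' @param pd a `phase_diff_set`.
#' @param bin_ms bin width in ms; must divide `2 * window_ms` evenly.
#' @return A `phase_histogram`: list with `bin_left_ms`, `bin_right_ms`,
#'   `counts`, `rel_freq` (sums to 1 for nonempty sets), `empty` flag.
#' @export
phase_histogram <- function(pd, bin_ms = 100) {
  stopifnot(inherits(pd, "phase_diff_set"))
  w <- pd$window_ms
  nbin <- 2 * w / bin_ms
  if (abs(nbin - round(nbin)) > 1e-9)
    stop("bin_ms must divide the full window 2*", w, " evenly", call. = FALSE)
  nbin <- as.integer(round(nbin))
  edges <- seq(-w, w, by = bin_ms)
  x <- pd$diffs_ms
  idx <- pmin(floor((x + w) / bin_ms) + 1L, nbin)  # right edge joins last bin
  counts <- tabulate(idx, nbins = nbin)
  n <- length(x)
  structure(
    list(bin_left_ms = edges[-length(edges)], bin_right_ms = edges[-1],
         counts = counts,
         rel_freq = if (n) counts / n else rep(0, nbin),
         empty = n == 0L, dyad_id = pd$dyad_id),
    class = "phase_histogram")
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("<phase_histogram> %s: %d bins of %g ms%s\n",
              x$dyad_id %||% "?", length(x$counts),
              x$bin_right_ms[1] - x$bin_left_ms[1],
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' @export
as.data.frame.phase_histogram <- function(x, ...) {
  data.frame(bin_left_ms = x$bin_left_ms, bin_right_ms = x$bin_right_ms,
             rel_freq = x$rel_freq)
}

#' Mass of the phase-difference distribution near its center
#'
#' Fraction of synchrony events whose lag falls within `halfwidth_ms` of the
#' center — by default the set's mean lag, matching the "share of events
#' within +/- 300 ms of the mean phase difference" summary used to describe
#' how tightly a dyad's events cluster.
#'
#' @param pd a nonempty `phase_diff_set`.
#' @param halfwidth_ms half-width of the central window; default 300.
#' @param center `"mean"` (default) or `"zero"`.
#' @return Proportion in `[0, 1]`.
#' @export
central_mass <- function(pd, halfwidth_ms = 300, center = c("mean", "zero")) {
  stopifnot(inherits(pd, "phase_diff_set"))
  center <- match.arg(center)
  if (!length(pd$diffs_ms))
    stop("central_mass is undefined for an empty phase-difference set",
         call. = FALSE)
  c0 <- if (center == "mean") mean(pd$diffs_ms) else 0
  mean(abs(pd$diffs_ms - c0) <= halfwidth_ms)
}

#' Write a phase-difference set or histogram to CSV
#'
#' @param x a `phase_diff_set` (single `diff_ms` column) or
#'   `phase_histogram` (`bin_left_ms, bin_right_ms, rel_freq`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phase <- function(x, path) {
  df <- if (inherits(x, "phase_diff_set")) data.frame(diff_ms = x$diffs_ms)
        else if (inherits(x, "phase_histogram")) as.data.frame(x)
        else stop("unsupported object", call. = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
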