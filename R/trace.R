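#' Construct a triaxial accelerometer trace
#'
#' An `accel_trace` holds one participant's uniformly sampled triaxial
#' acceleration series. Units are carried but never interpreted: the pipeline
#' z-scores the magnitude, so g and m/s^2 give identical results downstream.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param ax,ay,az numeric acceleration per axis, same length as `time`.
#' @param participant_id character label for the wearer.
#' @param sample_rate_hz nominal sampling rate; defaults to the rate implied
#'   by the median inter-sample interval.
#' @param tol relative tolerance on the inter-sample interval when checking
#'   sampling regularity. Gaps that are whole multiples of the nominal
#'   interval are permitted (they count as missing samples, see
#'   [check_missing()]).
#'
#' @return An object of class `accel_trace`: a list with elements
#'   `participant_id`, `time`, `ax`, `ay`, `az`, `sample_rate_hz` and an
#'   attribute `missing_fraction` (filled in by [read_trace()] /
#'   [check_missing()]).
#' @seealso [read_trace()], [trim_to_window()], [check_missing()]
#' @export
accel_trace <- function(time, ax, ay, az, participant_id = "unknown",
                        sample_rate_hz = NULL, tol = 0.01) {
  time <- as.numeric(time)
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(time)
  if (n < 2L)
    stop("an accel_trace needs at least two samples", call. = FALSE)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("time, ax, ay, az must have equal length", call. = FALSE)
  if (anyNA(time))
    stop("timestamps must not be missing", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (is.null(sample_rate_hz)) sample_rate_hz <- 1 / median(dt)
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be a positive number", call. = FALSE)
  nominal <- 1 / sample_rate_hz
  # every interval must be close to an integer multiple of the nominal step;
  # multiples > 1 are dropped samples, handled by check_missing()
  mult <- dt / nominal
  if (any(abs(mult - round(mult)) > tol) || any(round(mult) < 1))
    stop("sampling is irregular: intervals are not multiples of 1/sample_rate_hz",
         call. = FALSE)
  structure(
    list(participant_id = as.character(participant_id),
         time = time, ax = ax, ay = ay, az = az,
         sample_rate_hz = sample_rate_hz),
    missing_fraction = 0,
    class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> participant %s: %d samples @ %.6g Hz, %.2f-%.2f s\n",
              x$participant_id, length(x$time), x$sample_rate_hz,
              x$time[1], x$time[length(x$time)]))
  mf <- attr(x, "missing_fraction")
  if (!is.null(mf) && mf > 0)
    cat(sprintf("  missing samples: %.2f%%\n", 100 * mf))
  invisible(x)
}

#' @export
length.accel_trace <- function(x) length(x$time)

#' Read an accelerometer CSV file
#'
#' Reads a header CSV with a time column and three axis columns into an
#' [accel_trace()]. The time column may be in seconds or milliseconds;
#' with `time_unit = "auto"` milliseconds are assumed when the median
#' inter-sample interval exceeds 0.5 (a 100 Hz trace has steps of 0.01 s or
#' 10 ms, so the heuristic is unambiguous for any plausible rate).
#'
#' Rows whose axis values are missing are kept as `NA` samples; rows dropped
#' entirely from the file show up as timestamp gaps. Both are accounted for
#' by [check_missing()].
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping the canonical names
#'   `time`, `ax`, `ay`, `az` to the file's column names.
#' @param participant_id label for the trace; defaults to the file name.
#' @param time_unit `"auto"`, `"s"` or `"ms"`.
#' @param sample_rate_hz nominal rate; inferred when `NULL`.
#' @return An [accel_trace()].
#' @export
read_trace <- function(path,
                       column_map = c(time = "time", ax = "ax", ay = "ay", az = "az"),
                       participant_id = NULL,
                       time_unit = c("auto", "s", "ms"),
                       sample_rate_hz = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop("malformed CSV '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  need <- c("time", "ax", "ay", "az")
  cols <- column_map[need]
  if (anyNA(cols) || !all(cols %in% names(df)))
    stop("CSV '", path, "' lacks required columns: ",
         paste(setdiff(cols, names(df)), collapse = ", "), call. = FALSE)
  tm <- as.numeric(df[[cols[["time"]]]])
  if (time_unit == "auto")
    time_unit <- if (median(diff(tm), na.rm = TRUE) > 0.5) "ms" else "s"
  if (time_unit == "ms") tm <- tm / 1000
  tr <- accel_trace(tm, df[[cols[["ax"]]]], df[[cols[["ay"]]]], df[[cols[["az"]]]],
                    participant_id = participant_id %||%
                      sub("\\.[^.]*$", "", basename(path)),
                    sample_rate_hz = sample_rate_hz)
  # record the missing fraction on read; enforcement is check_missing()'s job
  attr(tr, "missing_fraction") <- missing_fraction(tr)
  tr
}

#' Write an accelerometer trace to CSV
#'
#' Inverse of [read_trace()]: writes `time,ax,ay,az` with time in seconds at
#' full double precision, so a read-back reproduces the trace exactly.
#'
#' @param trace an [accel_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- data.frame(time = format(trace$time, digits = 17, trim = TRUE,
                                 scientific = FALSE),
                   ax = trace$ax, ay = trace$ay, az = trace$az)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trim a trace to the active recording window
#'
#' Keeps samples with `start_s <= t < end_s` (half-open, so adjacent windows
#' partition a recording without double-counting). The window length
#' `end_s - start_s` is the duration used for the density feature downstream.
#'
#' @param trace an [accel_trace()].
#' @param start_s,end_s window delimiters in seconds (`end_s > start_s`).
#' @return The trimmed [accel_trace()], with attributes `window_start` and
#'   `window_end` recording the window.
#' @export
trim_to_window <- function(trace, start_s, end_s) {
  stopifnot(inherits(trace, "accel_trace"))
  if (!is.finite(start_s) || !is.finite(end_s) || end_s <= start_s)
    stop("invalid window: need end_s > start_s", call. = FALSE)
  keep <- trace$time >= start_s & trace$time < end_s
  if (!any(keep))
    stop("window [", start_s, ", ", end_s, ") does not overlap the trace",
         call. = FALSE)
  out <- trace
  out$time <- trace$time[keep]
  out$ax <- trace$ax[keep]; out$ay <- trace$ay[keep]; out$az <- trace$az[keep]
  attr(out, "missing_fraction") <- missing_fraction(out)
  attr(out, "window_start") <- start_s
  attr(out, "window_end") <- end_s
  out
}

# fraction of expected samples (on the nominal grid between the first and last
# timestamp) that are absent or NA on any axis
missing_fraction <- function(trace) {
  dt <- 1 / trace$sample_rate_hz
  n_expected <- round((trace$time[length(trace$time)] - trace$time[1]) / dt) + 1
  n_absent <- n_expected - length(trace$time)
  n_na <- sum(!complete.cases(trace$ax, trace$ay, trace$az))
  (n_absent + n_na) / n_expected
}

#' Enforce the missing-data exclusion rule
#'
#' Sessions with more than `max_missing_fraction` of their samples missing
#' (default 5%) are rejected. Short gaps of at most `max_gap_samples`
#' consecutive samples (30 ms at 100 Hz by default) are linearly interpolated
#' first and do not count toward the missing fraction, since they are
#' invisible after the 100 ms smoothing step. Missing samples are those
#' absent from the nominal time grid or recorded as `NA` on any axis.
#'
#' @param trace an [accel_trace()].
#' @param max_missing_fraction rejection threshold in `[0, 1]`; default 0.05.
#' @param max_gap_samples longest run of consecutive missing samples that is
#'   repaired by linear interpolation.
#' @return The validated trace, on the full nominal grid with short gaps
#'   interpolated, carrying an updated `missing_fraction` attribute.
#'   Rejection signals a condition of class `syncphase_session_rejected`
#'   whose `fraction` field holds the offending missing fraction.
#' @export
check_missing <- function(trace, max_missing_fraction = 0.05,
                          max_gap_samples = 3L) {
  stopifnot(inherits(trace, "accel_trace"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  dt <- 1 / trace$sample_rate_hz
  grid <- trace$time[1] + dt * seq(0, round((trace$time[length(trace$time)] -
                                               trace$time[1]) / dt))
  idx <- round((trace$time - trace$time[1]) / dt) + 1L
  put <- function(v) {
    out <- rep(NA_real_, length(grid)); out[idx] <- v; out
  }
  ax <- put(trace$ax); ay <- put(trace$ay); az <- put(trace$az)
  miss <- is.na(ax) | is.na(ay) | is.na(az)
  ax[miss] <- NA; ay[miss] <- NA; az[miss] <- NA

  # identify runs of consecutive missing samples; interpolate the short ones
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    interp_ok <- logical(length(grid))
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] <= max_gap_samples &&
          starts[k] > 1L && ends[k] < length(grid))
        interp_ok[starts[k]:ends[k]] <- TRUE
    }
    long_miss <- miss & !interp_ok
    frac <- sum(long_miss) / length(grid)
    if (frac > max_missing_fraction) {
      cond <- structure(
        class = c("syncphase_session_rejected", "error", "condition"),
        list(message = sprintf(
          "session rejected: %.1f%% of samples missing (limit %.1f%%)",
          100 * frac, 100 * max_missing_fraction),
          call = sys.call(-1), fraction = frac))
      stop(cond)
    }
    fill <- function(v) {
      ok <- !is.na(v)
      v[interp_ok] <- approx(grid[ok], v[ok], xout = grid[interp_ok])$y
      v
    }
    ax <- fill(ax); ay <- fill(ay); az <- fill(az)
    miss_after <- is.na(ax) | is.na(ay) | is.na(az)
  } else {
    miss_after <- miss
    frac <- 0
  }
  # long gaps survive as NA only when under threshold; carry them forward on
  # the grid so downstream stats use complete cases explicitly
  out <- trace
  out$time <- grid[!miss_after]
  out$ax <- ax[!miss_after]; out$ay <- ay[!miss_after]; out$az <- az[!miss_after]
  attr(out, "missing_fraction") <- frac
  attr(out, "window_start") <- attr(trace, "window_start")
  attr(out, "window_end") <- attr(trace, "window_end")
  out
}

#' Read a session manifest
#'
#' A manifest lists the dyad sessions of a study: for each session a
#' `dyad_id`, a `group` label (`TD` or `ASD`), `speaker_file` and
#' `listener_file` paths (resolved relative to the manifest), the active
#' recording window `start_time_s` / `end_time_s` delimited by the
#' synchronization claps, and an optional `covariates` map (e.g. AQ scores,
#' Likert ratings). YAML and JSON are both accepted, keyed on the file
#' extension.
#'
#' @param path manifest file (`.yaml`/`.yml` or `.json`). The top level is
#'   either a list of sessions or a map with a `sessions` entry.
#' @return A list of session records of class `sync_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = FALSE),
                stop("unsupported manifest format: .", ext, call. = FALSE))
  sessions <- if (!is.null(raw$sessions)) raw$sessions else raw
  base <- dirname(normalizePath(path))
  sessions <- lapply(sessions, function(s) {
    for (f in c("dyad_id", "group", "speaker_file", "listener_file",
                "start_time_s", "end_time_s"))
      if (is.null(s[[f]]))
        stop("manifest session missing field '", f, "'", call. = FALSE)
    if (!s$group %in% c("TD", "ASD"))
      stop("group must be 'TD' or 'ASD', got '", s$group, "'", call. = FALSE)
    if (s$end_time_s <= s$start_time_s)
      stop("session ", s$dyad_id, ": end_time_s must exceed start_time_s",
           call. = FALSE)
    for (f in c("speaker_file", "listener_file"))
      if (!grepl("^(/|[A-Za-z]:)", s[[f]]))
        s[[f]] <- file.path(base, s[[f]])
    s
  })
  structure(sessions, class = "sync_manifest")
}

#' @export
print.sync_manifest <- function(x, ...) {
  cat(sprintf("<sync_manifest> %d sessions (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(vapply(x, `[[`, "", "group"))),
                            table(vapply(x, `[[`, "", "group"))), collapse = ", ")))
  invisible(x)
}
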