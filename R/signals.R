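#' Evenly sampled physiological waveform
#'
#' Container for a uniformly sampled signal (resampled tachogram, respiration
#' or EDA waveform): numeric values, a sampling rate in Hz and a start time in
#' seconds. This is the substrate for the fractal-dimension, permutation-entropy
#' and spectral estimators.
#'
#' @param values Numeric vector of samples (signal units); all finite, length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds (default 0).
#' @return An object of class `uniform_signal` with fields `values`, `fs`, `t0`.
#' @examples
#' s <- uniform_signal(sin(2 * pi * 0.1 * seq(0, 60, by = 0.25)), fs = 4)
#' s
#' @export
uniform_signal <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("uniform_signal needs at least 2 samples")
  if (!all(is.finite(values))) stop("uniform_signal values must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  structure(list(values = values, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples @ %g Hz (%.1f s), range [%.4g, %.4g]\n",
              length(x$values), x$fs, length(x$values) / x$fs,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$values)

#' Sample times of a uniform signal
#' @param x A `uniform_signal`.
#' @return Numeric vector of sample times (s), starting at `t0`.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Physiologically timed interval series
#'
#' An event series is a sequence of positive durations with the event times at
#' which they end: RR intervals in milliseconds, or breath intervals (inbreath,
#' outbreath, peak-to-peak) in seconds. Times are reconstructed as the
#' cumulative sum of the intervals, starting at `t0`, so
#' `times[i+1] - times[i]` always equals `intervals[i+1]` in seconds.
#'
#' @param intervals Positive durations; ms for kind `"RRi"`, s otherwise.
#' @param kind One of `"RRi"`, `"IN"`, `"OUT"`, `"PP"`.
#' @param t0 Time origin in seconds (default 0).
#' @return An object of class `event_series` with fields `intervals`, `times`
#'   (event end-times, s), `kind`, `units`.
#' @examples
#' event_series(c(1000, 1000, 1000), kind = "RRi")  # beats at 1, 2, 3 s
#' @export
event_series <- function(intervals, kind = c("RRi", "IN", "OUT", "PP"), t0 = 0) {
  kind <- match.arg(kind)
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1L) stop("event_series needs at least one interval")
  bad <- which(!is.finite(intervals) | intervals <= 0)
  if (length(bad))
    stop(sprintf("non-positive or non-finite interval at position %d", bad[1L]))
  units <- if (kind == "RRi") "ms" else "s"
  scale <- if (units == "ms") 1e-3 else 1
  times <- t0 + cumsum(intervals) * scale
  structure(list(intervals = intervals, times = times, kind = kind,
                 units = units, t0 = as.numeric(t0)),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series:%s> %d intervals (%s), span %.1f s, mean %.4g %s\n",
              x$kind, length(x$intervals), x$units,
              x$times[length(x$times)] - x$t0, mean(x$intervals), x$units))
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$intervals)

#' Read an interval series or waveform from a text/CSV file
#'
#' Accepts a one-column plain-text file (one value per line, optional header)
#' or a CSV whose first numeric column is used. Interval files are unitless
#' numbers; `kind` declares the units (RRi in ms, breath intervals in s).
#' Waveforms (`kind = "waveform"`) additionally require a sampling rate.
#'
#' @param path File to read.
#' @param kind `"RRi"`, `"IN"`, `"OUT"`, `"PP"` for event series, or
#'   `"waveform"` for a uniformly sampled signal.
#' @param fs Sampling rate (Hz); required and used only for waveforms.
#' @return An [event_series()] or [uniform_signal()].
#' @export
read_series <- function(path, kind = c("RRi", "IN", "OUT", "PP", "waveform"),
                        fs = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  first_field <- function(l) trimws(strsplit(l, ",", fixed = TRUE)[[1L]][1L])
  fields <- vapply(lines, first_field, character(1L), USE.NAMES = FALSE)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[1L])))) start <- 2L  # header
  if (start > length(fields)) stop("no data rows in ", path)
  vals <- suppressWarnings(as.numeric(fields[start:length(fields)]))
  if (anyNA(vals)) {
    line_no <- start + which(is.na(vals))[1L] - 1L
    stop(sprintf("non-numeric value at line %d of %s", line_no, path))
  }
  if (kind == "waveform") {
    if (is.null(fs)) stop("fs is required for waveform input")
    return(uniform_signal(vals, fs = fs))
  }
  bad <- which(vals <= 0)
  if (length(bad))
    stop(sprintf("non-positive interval at line %d of %s", start + bad[1L] - 1L, path))
  event_series(vals, kind = kind)
}

.TRIAL_LEVELS <- c("Baseline", "Self", "5", "5.5", "6", "6.5", "7", "RBR")

#' Validate a long-format trial table
#'
#' The cohort result layout: one row per (participant, trial, duration,
#' measure), with trial labels drawn from the fixed protocol set (Baseline,
#' Self, the five paced rates in breaths per minute, and the composite RBR
#' trial).
#'
#' @param df Data frame with columns `participant`, `trial`, `duration`,
#'   `measure_id`, `value`.
#' @return The validated data frame (invisibly classed `trial_table`).
#' @export
trial_table <- function(df) {
  need <- c("participant", "trial", "duration", "measure_id", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial_table missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  bad <- setdiff(unique(as.character(df$trial)), .TRIAL_LEVELS)
  if (length(bad)) stop("unknown trial labels: ", paste(bad, collapse = ", "))
  key <- do.call(paste, c(df[c("participant", "trial", "duration", "measure_id")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate trial_table key: ", gsub("\r", " / ", d, fixed = TRUE))
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Write a trial table as a deterministic long-format CSV
#'
#' Fixed column order and header; rows sorted by (participant, trial,
#' duration, measure_id) so output is byte-stable. Values are written with
#' full precision (15 significant digits).
#'
#' @param table A [trial_table()] (or data frame accepted by it).
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_results <- function(table, path) {
  df <- trial_table(table)
  trial_ord <- match(as.character(df$trial), .TRIAL_LEVELS)
  ord <- order(df$participant, trial_ord, df$duration, df$measure_id)
  df <- df[ord, , drop = FALSE]
  df$value <- formatC(df$value, digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a long-format results CSV
#'
#' @param path CSV produced by [write_results()].
#' @return A [trial_table()].
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(trial = "character"))
  trial_table(df)
}
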