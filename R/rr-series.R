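#' RR-interval series
#'
#' An `rr_series` holds a subject's beat-to-beat (RR) intervals in
#' milliseconds together with the beat times in seconds. The convention is
#' that the recording starts at time 0 and each interval ends at its beat,
#' so `beat_times == cumsum(intervals) / 1000` (up to an optional origin
#' offset for phase segments cut out of a longer recording).
#'
#' @param intervals numeric vector of RR intervals in ms (all `> 0`).
#' @param beat_times optional numeric vector of beat times in s; must be
#'   strictly increasing and consistent with `intervals` to < 0.5 ms. When
#'   omitted it is reconstructed by cumulative summation from 0.
#' @return An object of class `rr_series` with elements `intervals` (ms),
#'   `beat_times` (s) and `n` (number of beats).
#' @examples
#' rr <- rr_series(c(800, 810, 790))
#' rr$beat_times # 0.80 1.61 2.40
#' @export
rr_series <- function(intervals, beat_times = NULL) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L)
    stop("rr_series needs at least 2 intervals", call. = FALSE)
  if (anyNA(intervals) || any(!is.finite(intervals)))
    stop("RR intervals must be finite", call. = FALSE)
  if (any(intervals <= 0))
    stop("RR intervals must be positive", call. = FALSE)
  if (is.null(beat_times)) {
    beat_times <- cumsum(intervals) / 1000
  } else {
    beat_times <- as.numeric(beat_times)
    if (length(beat_times) != length(intervals))
      stop("beat_times and intervals must have equal length", call. = FALSE)
    if (any(diff(beat_times) <= 0))
      stop("beat_times must be strictly increasing", call. = FALSE)
    implied <- diff(c(beat_times[1] - intervals[1] / 1000, beat_times)) * 1000
    if (max(abs(implied - intervals)) >= 0.5)
      stop("beat_times inconsistent with intervals (>= 0.5 ms)", call. = FALSE)
  }
  structure(list(intervals = intervals, beat_times = beat_times,
                 n = length(intervals)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, %.1f s, mean RR %.1f ms\n",
              x$n, diff(range(x$beat_times)) + x$intervals[1] / 1000,
              mean(x$intervals)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) x$n

#' Read an RR recording from disk
#'
#' Two plain-text layouts are supported: `"plain"`, one RR interval in ms per
#' line (the common chest-strap export), and `"csv"`, a comma-separated file
#' with header columns `time_s,rr_ms`. With `format = "auto"` a file whose
#' first line contains a comma or letters is treated as CSV.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"plain"`, `"csv"`.
#' @return An [rr_series].
#' @export
read_rr <- function(path, format = c("auto", "plain", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error: empty RR file ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("[,A-Za-z]", lines[1])) "csv" else "plain"
  }
  if (format == "plain") {
    vals <- suppressWarnings(as.numeric(lines))
    bad <- which(is.na(vals) | vals <= 0)
    if (length(bad))
      stop(sprintf("parse error at line %d of %s: %s", bad[1], path,
                   lines[bad[1]]), call. = FALSE)
    rr_series(vals)
  } else {
    dat <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
    if (!all(c("time_s", "rr_ms") %in% names(dat)))
      stop("parse error: CSV must have columns time_s,rr_ms", call. = FALSE)
    bad <- which(!is.finite(dat$rr_ms) | dat$rr_ms <= 0)
    if (length(bad))
      stop(sprintf("parse error at line %d of %s: non-positive rr_ms",
                   bad[1] + 1L, path), call. = FALSE)
    rr_series(dat$rr_ms, beat_times = dat$time_s)
  }
}

#' Write an RR series to disk
#'
#' @param rr an [rr_series].
#' @param path output file path.
#' @param format `"plain"` (one ms value per line) or `"csv"`
#'   (`time_s,rr_ms` with header).
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path, format = c("plain", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(rr, "rr_series"))
  if (format == "plain") {
    writeLines(format(rr$intervals, scientific = FALSE, trim = TRUE,
                      digits = 15), path)
  } else {
    utils::write.csv(data.frame(time_s = rr$beat_times, rr_ms = rr$intervals),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
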