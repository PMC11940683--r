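#' Resample an RR series to an even grid
#'
#' Interpolates the RR intervals against their beat times with a cubic
#' spline and evaluates on an even grid spanning the observed beats (no
#' extrapolation); the conventional step before FFT-based spectral analysis.
#'
#' @param rr an [rr_series] with at least 4 beats (corrected).
#' @param sample_rate grid rate, Hz (default 4).
#' @return A `tachogram`: list with `values` (ms), `sample_rate`, `origin`
#'   (time of the first grid point, s) and `detrended` flag. Grid length is
#'   `floor((t_last - t_first) * sample_rate) + 1`.
#' @export
resample_tachogram <- function(rr, sample_rate = 4) {
  stopifnot(inherits(rr, "rr_series"))
  if (rr$n < 4L) stop("need at least 4 beats to resample", call. = FALSE)
  t <- rr$beat_times
  len <- floor((t[rr$n] - t[1]) * sample_rate) + 1L
  grid <- t[1] + (seq_len(len) - 1L) / sample_rate
  vals <- stats::spline(t, rr$intervals, xout = grid, method = "fmm")$y
  structure(list(values = vals, sample_rate = sample_rate, origin = t[1],
                 detrended = FALSE),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d samples @ %g Hz%s\n", length(x$values),
              x$sample_rate, if (x$detrended) ", detrended" else ""))
  invisible(x)
}

#' Smoothness-priors detrending
#'
#' Removes slow nonstationary trends with the regularized operator
#' `trend = (I + lambda^2 t(D2) D2)^-1 x`, where `D2` is the second-difference
#' matrix; the residual `x - trend` is a high-pass filtered series whose
#' cutoff is set by `lambda` (500 at 4 Hz passes the 0.04-0.4 Hz HRV bands
#' essentially untouched). Straight lines lie in the null space of `D2` and
#' are removed exactly. The solve uses a sparse banded factorization.
#'
#' @param tach a [resample_tachogram()] output (even sampling required).
#' @param lam smoothing parameter `lambda` (default 500; 0 returns the input
#'   as trend and a zero residual).
#' @return List with `trend` and `residual`, both `tachogram` objects;
#'   `residual$detrended` is `TRUE`.
#' @export
detrend_smoothness_priors <- function(tach, lam = 500) {
  stopifnot(inherits(tach, "tachogram"))
  x <- tach$values
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to detrend", call. = FALSE)
  if (lam < 0) stop("lam must be non-negative", call. = FALSE)
  if (lam == 0) {
    trend <- x
  } else {
    ones <- rep(1, n - 2L)
    D2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                             diagonals = list(ones, -2 * ones, ones))
    A <- Matrix::Diagonal(n) + lam^2 * Matrix::crossprod(D2)
    trend <- as.numeric(Matrix::solve(A, x))
  }
  mk <- function(v, det) {
    out <- tach
    out$values <- v
    out$detrended <- det
    out
  }
  list(trend = mk(trend, FALSE), residual = mk(x - trend, TRUE))
}

#' Extract a centered analysis segment from a phase
#'
#' Cuts a fixed-length window out of an annotated phase so that epochs are
#' comparable across phases: the preferred 5-minute window when the phase is
#' long enough, otherwise a 3-minute fallback; shorter phases are rejected.
#' The window is centered in the phase to avoid boundary transients.
#'
#' @param recording an `rr_recording` (see [simulate_recording()]), or any
#'   list with elements `rr` ([rr_series]) and `phases`
#'   (data.frame `phase,start_s,end_s`).
#' @param phase one of the annotated phase names.
#' @param preferred_s preferred window length, s (default 300).
#' @param fallback_s fallback window length, s (default 180).
#' @return An [rr_series] of the beats inside the window, with attributes
#'   `window_s`, `fallback` and `phase`.
#' @export
extract_phase_segment <- function(recording, phase, preferred_s = 300,
                                  fallback_s = 180) {
  ann <- recording$phases
  row <- ann[ann$phase == phase, , drop = FALSE]
  if (nrow(row) != 1L) stop("phase not annotated: ", phase, call. = FALSE)
  dur <- row$end_s - row$start_s
  if (dur >= preferred_s) {
    w <- preferred_s; fb <- FALSE
  } else if (dur >= fallback_s) {
    w <- fallback_s; fb <- TRUE
  } else {
    stop(sprintf("segment unavailable: phase '%s' (%.0f s) shorter than %.0f s",
                 phase, dur, fallback_s), call. = FALSE)
  }
  mid <- (row$start_s + row$end_s) / 2
  w0 <- mid - w / 2
  w1 <- mid + w / 2
  bt <- recording$rr$beat_times
  sel <- which(bt > w0 + 1e-9 & bt <= w1 + 1e-9)
  if (length(sel) < 2L)
    stop("segment unavailable: too few beats in window", call. = FALSE)
  seg <- rr_series(recording$rr$intervals[sel], beat_times = bt[sel])
  attr(seg, "window_s") <- w
  attr(seg, "fallback") <- fb
  attr(seg, "phase") <- phase
  seg
}
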