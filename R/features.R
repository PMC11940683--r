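#' Time-domain HRV features
#'
#' @param segment an [rr_series] (artifact-corrected) with >= 10 beats.
#' @return List with `mean_rr` (ms), `mean_hr` (bpm, mean of the per-beat
#'   instantaneous rate `60000/RR`), `hr_range` (max - min instantaneous HR,
#'   bpm) and `sdnn` (sample standard deviation of the intervals, ms).
#' @examples
#' time_domain_features(rr_series(rep(1000, 12)))$mean_hr # 60
#' @export
time_domain_features <- function(segment) {
  stopifnot(inherits(segment, "rr_series"))
  if (segment$n < 10L) stop("need at least 10 beats", call. = FALSE)
  x <- segment$intervals
  hr <- 60000 / x
  list(mean_rr = mean(x), mean_hr = mean(hr),
       hr_range = max(hr) - min(hr), sdnn = stats::sd(x))
}

#' Welch power spectral density of a tachogram
#'
#' Averages Hann-tapered, 50%-overlapped periodograms. The normalization is
#' Parseval-calibrated: the integral of the one-sided density over frequency
#' equals the (per-segment demeaned) variance of the input, so band integrals
#' are powers in ms^2. When the series is shorter than the requested window,
#' a single window equal to the series length is used and flagged.
#'
#' @param tach a detrended [resample_tachogram()] output.
#' @param window_s window length, s (default 300).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return A `spectral_estimate`: list with `freq` (Hz), `density` (ms^2/Hz),
#'   `window_s` (actual), `overlap`, `taper`, `n_segments`, `single_window`.
#' @export
welch_psd <- function(tach, window_s = 300, overlap = 0.5) {
  stopifnot(inherits(tach, "tachogram"))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  fs <- tach$sample_rate
  x <- tach$values
  n <- length(x)
  if (n < 60 * fs) stop("segment shorter than 60 s", call. = FALSE)
  L <- round(window_s * fs)
  single <- FALSE
  if (n < L) {
    L <- n
    single <- TRUE
  }
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1)) # Hann
  wnorm <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    p <- (Mod(X[seq_len(nf)])^2) / (fs * wnorm)
    # one-sided: double everything except DC (and Nyquist when L even)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (L %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  structure(list(freq = (seq_len(nf) - 1L) * fs / L,
                 density = acc / length(starts),
                 window_s = L / fs, overlap = overlap, taper = "hann",
                 n_segments = length(starts), single_window = single),
            class = "spectral_estimate")
}

# trapezoidal integral of the density over [f1, f2], interpolating the edges
integrate_band <- function(freq, density, f1, f2) {
  f1 <- max(f1, freq[1])
  f2 <- min(f2, freq[length(freq)])
  if (f2 <= f1) return(0)
  inside <- freq > f1 & freq < f2
  fx <- c(f1, freq[inside], f2)
  fy <- c(stats::approx(freq, density, f1)$y, density[inside],
          stats::approx(freq, density, f2)$y)
  sum(diff(fx) * (fy[-1] + fy[-length(fy)]) / 2)
}

#' Band powers and autonomic-balance indices
#'
#' Integrates the spectral density over the VLF, LF and HF bands and derives
#' the index vocabulary used throughout the package: normalized units
#' (`lf_nu = 100 * lf/(lf+hf)`), the LF/HF ratio, the combined oscillatory
#' power `lhfp = lf + hf`, and the bounded balance index
#' `lhfnd = (lf - hf)/(lf + hf)`, which equals `(lf_nu - hf_nu)/100`.
#'
#' @param spec a [welch_psd()] output.
#' @param bands numeric vector of band edges in Hz:
#'   `c(vlf_lo, vlf_hi, lf_hi, hf_hi)`; `vlf_hi`/`lf_hi` double as the
#'   LF/HF lower edges. Default `c(0.003, 0.04, 0.15, 0.40)`.
#' @return A `band_powers` list: `vlf`, `lf`, `hf`, `total` (ms^2), `lf_nu`,
#'   `hf_nu` (percent), `lf_hf_ratio`, `lhfp` (ms^2), `lhfnd`.
#' @export
band_powers <- function(spec, bands = c(0.003, 0.04, 0.15, 0.40)) {
  stopifnot(inherits(spec, "spectral_estimate"), length(bands) == 4L,
            all(diff(bands) > 0))
  vlf <- integrate_band(spec$freq, spec$density, bands[1], bands[2])
  lf <- integrate_band(spec$freq, spec$density, bands[2], bands[3])
  hf <- integrate_band(spec$freq, spec$density, bands[3], bands[4])
  if (lf + hf <= 0)
    stop("lhfnd undefined: lf + hf = 0", call. = FALSE)
  bd <- to_bidim(lf, hf)
  structure(list(vlf = vlf, lf = lf, hf = hf, total = vlf + lf + hf,
                 lf_nu = 100 * lf / (lf + hf), hf_nu = 100 * hf / (lf + hf),
                 lf_hf_ratio = if (hf > 0) lf / hf else Inf,
                 lhfp = bd$lhfp, lhfnd = bd$lhfnd),
            class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf("<band_powers> VLF %.1f  LF %.1f  HF %.1f ms^2 | LHFP %.1f  LHFND %.3f\n",
              x$vlf, x$lf, x$hf, x$lhfp, x$lhfnd))
  invisible(x)
}

#' Per-subject, per-phase HRV feature table
#'
#' Runs the full per-segment pipeline — centered segment extraction, artifact
#' correction, time-domain features, 4 Hz resampling, smoothness-priors
#' detrending, Welch spectrum, band integration — for every recording and
#' phase. Segments that fail a quality gate are kept as rows with a flag
#' rather than silently dropped: `excluded` when the corrected-beat
#' percentage reaches 5%, `fallback` when the 3-minute window was used,
#' `missing:<reason>` when no segment could be produced.
#'
#' @param recordings named list of `rr_recording` objects.
#' @param phases phase names to extract (default `pre`, `interview`, `post`).
#' @param lam detrending parameter (default 500).
#' @param sample_rate tachogram rate, Hz (default 4).
#' @param window_s,overlap Welch settings (defaults 300 s, 0.5).
#' @param preferred_s,fallback_s segment policy (defaults 300 s / 180 s).
#' @param bands band edges, see [band_powers()].
#' @param correct run artifact detection/correction (default TRUE).
#' @return A data.frame with columns `subject, phase, mean_rr, mean_hr,
#'   hr_range, sdnn, vlf, lf, hf, total, lf_nu, hf_nu, lf_hf, lhfp, lhfnd,
#'   corrected_pct, seg_s, flags`.
#' @export
compute_feature_table <- function(recordings,
                                  phases = c("pre", "interview", "post"),
                                  lam = 500, sample_rate = 4,
                                  window_s = 300, overlap = 0.5,
                                  preferred_s = 300, fallback_s = 180,
                                  bands = c(0.003, 0.04, 0.15, 0.40),
                                  correct = TRUE) {
  ids <- names(recordings)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(recordings))
  rows <- vector("list", length(recordings) * length(phases))
  k <- 0L
  na_row <- function(id, ph, flag) {
    data.frame(subject = id, phase = ph, mean_rr = NA_real_,
               mean_hr = NA_real_, hr_range = NA_real_, sdnn = NA_real_,
               vlf = NA_real_, lf = NA_real_, hf = NA_real_, total = NA_real_,
               lf_nu = NA_real_, hf_nu = NA_real_, lf_hf = NA_real_,
               lhfp = NA_real_, lhfnd = NA_real_, corrected_pct = NA_real_,
               seg_s = NA_real_, flags = flag, stringsAsFactors = FALSE)
  }
  for (i in seq_along(recordings)) {
    for (ph in phases) {
      k <- k + 1L
      rows[[k]] <- tryCatch({
        seg <- extract_phase_segment(recordings[[i]], ph, preferred_s,
                                     fallback_s)
        flags <- character(0)
        seg_w <- attr(seg, "window_s")
        if (isTRUE(attr(seg, "fallback"))) flags <- c(flags, "fallback")
        pct <- 0
        if (correct) {
          corr <- suppressWarnings(detect_and_correct_artifacts(seg))
          pct <- corr$labels$corrected_pct
          if (pct >= 5) flags <- c(flags, "excluded")
          seg <- corr$rr
        }
        td <- time_domain_features(seg)
        tach <- resample_tachogram(seg, sample_rate)
        det <- detrend_smoothness_priors(tach, lam)
        spec <- welch_psd(det$residual, window_s, overlap)
        bp <- band_powers(spec, bands)
        data.frame(subject = ids[i], phase = ph, mean_rr = td$mean_rr,
                   mean_hr = td$mean_hr, hr_range = td$hr_range,
                   sdnn = td$sdnn, vlf = bp$vlf, lf = bp$lf, hf = bp$hf,
                   total = bp$total, lf_nu = bp$lf_nu, hf_nu = bp$hf_nu,
                   lf_hf = bp$lf_hf_ratio, lhfp = bp$lhfp, lhfnd = bp$lhfnd,
                   corrected_pct = pct,
                   seg_s = seg_w %||% spec$window_s,
                   flags = paste(flags, collapse = ";"),
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        na_row(ids[i], ph, paste0("missing:", conditionMessage(e)))
      })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
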