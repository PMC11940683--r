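#' Oscillatory RR modulator specification
#'
#' Describes the instantaneous RR-interval signal driving the IPFM beat
#' generator: a mean level plus one low-frequency (LF, 0.04-0.15 Hz) and one
#' high-frequency (HF, 0.15-0.4 Hz) sinusoid and broadband noise. A sinusoid
#' of amplitude `a` ms contributes a band power of `a^2 / 2` ms^2 to the
#' tachogram spectrum, which is what makes these simulations usable as
#' ground truth for spectral estimators.
#'
#' @param mean_rr mean RR interval, ms (> 0).
#' @param lf_freq LF oscillation frequency, Hz, in `[0.04, 0.15)`.
#' @param lf_amp LF amplitude, ms (>= 0).
#' @param hf_freq HF oscillation frequency, Hz, in `[0.15, 0.4]`.
#' @param hf_amp HF amplitude, ms (>= 0).
#' @param noise_sd standard deviation of broadband noise on the modulator,
#'   ms. The noise is white on a 4 Hz grid and linearly interpolated, so its
#'   power is spread approximately flat over 0-2 Hz.
#' @param lf_phase,hf_phase oscillator phases, radians.
#' @return A `modulator_spec` object.
#' @export
modulator_spec <- function(mean_rr, lf_freq = 0.10, lf_amp = 0,
                           hf_freq = 0.25, hf_amp = 0, noise_sd = 0,
                           lf_phase = 0, hf_phase = 0) {
  if (!is.finite(mean_rr) || mean_rr <= 0)
    stop("mean_rr must be positive", call. = FALSE)
  if (lf_amp < 0 || hf_amp < 0 || noise_sd < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  if (lf_freq < 0.04 || lf_freq >= 0.15)
    stop("lf_freq must lie in [0.04, 0.15)", call. = FALSE)
  if (hf_freq < 0.15 || hf_freq > 0.4)
    stop("hf_freq must lie in [0.15, 0.4]", call. = FALSE)
  structure(list(mean_rr = mean_rr, lf_freq = lf_freq, lf_amp = lf_amp,
                 hf_freq = hf_freq, hf_amp = hf_amp, noise_sd = noise_sd,
                 lf_phase = lf_phase, hf_phase = hf_phase),
            class = "modulator_spec")
}

#' Deterministic part of the RR modulator
#'
#' Evaluates the noise-free instantaneous RR signal of a [modulator_spec] at
#' times `t`; used as the ground-truth oracle when checking tachogram
#' reconstruction fidelity.
#'
#' @param mod a [modulator_spec].
#' @param t times, s.
#' @return RR values, ms.
#' @export
eval_modulator <- function(mod, t) {
  mod$mean_rr +
    mod$lf_amp * sin(2 * pi * mod$lf_freq * t + mod$lf_phase) +
    mod$hf_amp * sin(2 * pi * mod$hf_freq * t + mod$hf_phase)
}

#' Generate beat times by integral pulse frequency modulation
#'
#' Integrates the instantaneous beat rate `1000 / rr(t)` (beats/s) and emits
#' a beat each time the integral crosses an integer threshold; crossing times
#' are located by linear interpolation on the integration grid, so beats are
#' not quantized to the grid. With zero amplitudes and zero noise the output
#' is exactly periodic at `mean_rr`.
#'
#' @param mod a [modulator_spec].
#' @param duration_s recording length, s; must cover at least 10 beats.
#' @param seed optional integer seed (only consumed when `noise_sd > 0`).
#' @param dt integration grid step, s.
#' @return Numeric vector of beat times (s), strictly increasing, within
#'   `(0, duration_s]`.
#' @export
ipfm_beat_times <- function(mod, duration_s, seed = NULL, dt = 0.125) {
  stopifnot(inherits(mod, "modulator_spec"))
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be positive", call. = FALSE)
  if (duration_s < 10 * mod$mean_rr / 1000)
    stop("duration_s must cover at least 10 mean RR intervals", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  tg <- seq(0, duration_s, by = dt)
  if (tg[length(tg)] < duration_s) tg <- c(tg, duration_s)
  rr_t <- eval_modulator(mod, tg)
  if (mod$noise_sd > 0) {
    # white noise on a 4 Hz grid, linearly interpolated onto the
    # integration grid: approximately flat spectrum over 0-2 Hz
    tn <- seq(0, duration_s + 0.25, by = 0.25)
    noise <- stats::rnorm(length(tn), 0, mod$noise_sd)
    rr_t <- rr_t + stats::approx(tn, noise, xout = tg)$y
  }
  rr_t <- pmax(rr_t, 0.05 * mod$mean_rr) # guard against non-positive rate
  rate <- 1000 / rr_t                    # beats per second

  # cumulative trapezoidal integral of the rate
  n <- length(tg)
  incr <- diff(tg) * (rate[-1] + rate[-n]) / 2
  cum <- c(0, cumsum(incr))

  n_beats <- floor(cum[n])
  if (n_beats < 1L) return(numeric(0))
  thresholds <- seq_len(n_beats)
  # invert the monotone integral at integer thresholds
  beats <- stats::approx(cum, tg, xout = thresholds, ties = "ordered")$y
  beats
}
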