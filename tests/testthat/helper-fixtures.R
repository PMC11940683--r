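# shared fixtures, all generated in code

constant_series <- function(n = 300, rr = 800) {
  rr_series(rep(rr, n))
}

# IPFM series with the default stress-protocol style modulation
ipfm_series <- function(mean_rr = 680, lf_amp = sqrt(2 * 643),
                        hf_amp = sqrt(2 * 295), noise_sd = 10,
                        duration = 600, seed = 1) {
  mod <- modulator_spec(mean_rr, lf_amp = lf_amp, hf_amp = hf_amp,
                        noise_sd = noise_sd)
  b <- ipfm_beat_times(mod, duration, seed = seed)
  rr_series(diff(c(0, b)) * 1000, beat_times = b)
}

# tachogram wrapper around raw values
raw_tachogram <- function(values, fs = 4, detrended = TRUE) {
  structure(list(values = values, sample_rate = fs, origin = 0,
                 detrended = detrended),
            class = "tachogram")
}

# detection scores against ground truth (match within +/- 1 beat)
detection_scores <- function(truth_idx, detected_idx, n_beats) {
  hit <- vapply(truth_idx, function(i) any(abs(detected_idx - i) <= 1), TRUE)
  fp <- vapply(detected_idx, function(d) all(abs(truth_idx - d) > 1), TRUE)
  list(tp = sum(hit), fn = sum(!hit), fp = sum(fp),
       n_normal = n_beats - length(truth_idx))
}

# minimal recording built by hand (constant rate, arbitrary phase table)
manual_recording <- function(durations, rr_ms = 800) {
  total <- sum(durations)
  n <- floor(total * 1000 / rr_ms)
  rr <- rr_series(rep(rr_ms, n))
  ends <- cumsum(durations)
  phases <- data.frame(phase = names(durations),
                       start_s = c(0, ends[-length(ends)]), end_s = ends,
                       stringsAsFactors = FALSE)
  structure(list(rr = rr, phases = phases, meta = NULL),
            class = "rr_recording")
}
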