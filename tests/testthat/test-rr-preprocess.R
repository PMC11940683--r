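test_that("artifact-free input yields zero corrections", {
  out <- detect_and_correct_artifacts(constant_series(300))
  expect_identical(out$labels$n_corrected, 0L)
  expect_equal(out$labels$corrected_pct, 0)
  expect_identical(out$rr$intervals, constant_series(300)$intervals)
})

test_that("a merged pair is recognized as a missed beat and split", {
  x <- rep(800, 200)
  x[100] <- 1600
  rr <- rr_series(x)
  out <- detect_and_correct_artifacts(rr)
  expect_identical(out$labels$category[100], "missed")
  expect_identical(out$labels$n_corrected, 1L)
  expect_equal(out$labels$corrected_pct, 100 / 200)
  expect_equal(out$rr$n, 201L)
  expect_equal(out$rr$intervals[100:101], c(800, 800))
  expect_equal(sum(out$rr$intervals), sum(x), tolerance = 1e-9)
})

test_that("detection recovers injected artifacts with few false positives", {
  # quick 5-seed check; the full 50-seed fidelity study runs in acceptance
  tp <- fn <- fp <- nn <- 0
  for (s in 1:5) {
    rr <- ipfm_series(seed = s)
    inj <- inject_artifacts(rr, artifact_spec(), seed = s + 100)
    out <- suppressWarnings(detect_and_correct_artifacts(inj$rr))
    det <- which(out$labels$category != "normal")
    sc <- detection_scores(inj$truth$index, det, inj$rr$n)
    tp <- tp + sc$tp; fn <- fn + sc$fn; fp <- fp + sc$fp; nn <- nn + sc$n_normal
    expect_lt(abs(sum(out$rr$intervals) - sum(inj$rr$intervals)), 1)
  }
  expect_gte(tp / (tp + fn), 0.85)
  expect_lte(fp / nn, 0.03)
})

test_that("correction is idempotent to within 0.5% of beats", {
  for (s in 1:3) {
    rr <- ipfm_series(seed = s)
    inj <- inject_artifacts(rr, artifact_spec(), seed = s)
    once <- suppressWarnings(detect_and_correct_artifacts(inj$rr))
    twice <- suppressWarnings(detect_and_correct_artifacts(once$rr))
    expect_lt(twice$labels$n_corrected / once$rr$n, 0.005)
  }
})

test_that("heavy contamination trips the 5% quality warning", {
  x <- rep(800, 240)
  x[seq(10, 230, by = 12)] <- 1600 # ~8% merged beats
  expect_warning(out <- detect_and_correct_artifacts(rr_series(x)), "5%")
  expect_gte(out$labels$corrected_pct, 5)
})

test_that("short or invalid series are rejected", {
  expect_error(detect_and_correct_artifacts(constant_series(10)), "20 beats")
})

test_that("resampling reproduces constants and the grid arithmetic", {
  rr <- constant_series(100, 1000)
  tach <- resample_tachogram(rr)
  expect_true(all(abs(tach$values - 1000) < 1e-9))
  t_span <- rr$beat_times[rr$n] - rr$beat_times[1]
  expect_equal(length(tach$values), floor(t_span * 4) + 1)
  expect_error(resample_tachogram(rr_series(c(800, 900, 850))), "4 beats")
})

test_that("resampled tachogram tracks the true modulator", {
  mod <- modulator_spec(800, lf_amp = 40, noise_sd = 0)
  b <- ipfm_beat_times(mod, 300)
  rr <- rr_series(diff(c(0, b)) * 1000, beat_times = b)
  tach <- resample_tachogram(rr)
  grid <- tach$origin + (seq_along(tach$values) - 1L) / 4
  keep <- grid > 10 & grid < 290 # interior points
  # interval RR_i is the average rate over (t_{i-1}, t_i] plotted at t_i,
  # so the reconstruction trails the modulator by half a mean interval
  truth <- eval_modulator(mod, grid[keep] - 0.8 / 2)
  expect_lt(max(abs(tach$values[keep] - truth)), 0.05 * 40)
})

test_that("smoothness-priors detrending has the stated limits", {
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), 800, sd = 5)) + 800
  tach <- raw_tachogram(x, detrended = FALSE)
  # lambda = 0: identity
  d0 <- detrend_smoothness_priors(tach, 0)
  expect_identical(d0$trend$values, x)
  expect_true(all(d0$residual$values == 0))
  # straight line is removed exactly (null space of D2)
  line <- raw_tachogram(7 + 3 * seq_along(x), detrended = FALSE)
  dl <- detrend_smoothness_priors(line, 500)
  expect_lt(max(abs(dl$residual$values)), 1e-6)
  # 0.25 Hz sinusoid passes nearly untouched at lambda = 500
  ts <- raw_tachogram(30 * sin(2 * pi * 0.25 * (0:1199) / 4), detrended = FALSE)
  ds <- detrend_smoothness_priors(ts, 500)
  expect_gte(stats::var(ds$residual$values) / stats::var(ts$values), 0.95)
  expect_error(detrend_smoothness_priors(raw_tachogram(c(1, 2)), 500),
               "3 samples")
})

test_that("detrending is linear in its input", {
  set.seed(9)
  x <- rnorm(400)
  line <- 5 + 0.3 * seq_len(400)
  a <- 3.7
  r1 <- detrend_smoothness_priors(raw_tachogram(a * x + line, detrended = FALSE),
                                  500)$residual$values
  r2 <- detrend_smoothness_priors(raw_tachogram(x, detrended = FALSE),
                                  500)$residual$values
  expect_lt(max(abs(r1 - a * r2)) / max(abs(r2)), 1e-9)
})

test_that("sparse detrending solve matches the dense inverse", {
  set.seed(10)
  n <- 600
  x <- cumsum(rnorm(n)) + 800
  sp <- detrend_smoothness_priors(raw_tachogram(x, detrended = FALSE),
                                  500)$trend$values
  D2 <- diff(diag(n), differences = 2)
  dense <- solve(diag(n) + 500^2 * crossprod(D2), x)
  expect_lt(max(abs(sp - dense)) / max(abs(x)), 1e-8)
})

test_that("detrending residual suppresses the near-DC band", {
  set.seed(11)
  n <- 2400
  x <- 50 * sin(2 * pi * 0.005 * (0:(n - 1)) / 4) + rnorm(n)
  det <- detrend_smoothness_priors(raw_tachogram(x, detrended = FALSE), 500)
  pow_band <- function(v) {
    sp <- welch_psd(raw_tachogram(v), window_s = 300)
    hrvbal:::integrate_band(sp$freq, sp$density, 0, 0.01)
  }
  expect_lt(pow_band(det$residual$values) / pow_band(x), 0.05)
})

test_that("phase segments follow the 5-min / 3-min policy", {
  rec <- manual_recording(c(pre = 300, interview = 600, post = 240))
  seg <- extract_phase_segment(rec, "interview")
  expect_equal(attr(seg, "window_s"), 300)
  expect_false(attr(seg, "fallback"))
  # centered: beats inside (450, 750]
  expect_true(all(seg$beat_times > 450 & seg$beat_times <= 750 + 1e-9))
  segf <- extract_phase_segment(rec, "post")
  expect_equal(attr(segf, "window_s"), 180)
  expect_true(attr(segf, "fallback"))
  rec2 <- manual_recording(c(pre = 120, interview = 600, post = 300))
  expect_error(extract_phase_segment(rec2, "pre"), "unavailable")
})
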