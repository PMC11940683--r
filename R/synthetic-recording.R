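#' Three-phase recording protocol
#'
#' Defines the stress/recovery protocol a simulated recording follows: an
#' anticipation baseline (`pre`), a stressor (`interview`) and a recovery
#' baseline (`post`), each with its own duration and RR modulator. The
#' default modulators are calibrated to published short-term group means for
#' this kind of public-performance protocol: mean RR 680/586/708 ms and LF
#' band powers 643/449/1088 ms^2, HF 295/232/373 ms^2 across the three
#' phases (a sinusoid of amplitude `a` carries band power `a^2/2`, so the
#' default amplitudes are `sqrt(2 * power)`).
#'
#' @param durations named numeric vector of phase lengths in s; must have
#'   exactly the names `pre`, `interview`, `post`, in that order.
#' @param modulators named list of three [modulator_spec] objects, same names.
#' @param noise_sd broadband modulator noise used when building the default
#'   modulators, ms.
#' @return A `protocol_config` object.
#' @export
protocol_config <- function(durations = c(pre = 300, interview = 600, post = 300),
                            modulators = NULL, noise_sd = 10) {
  ph <- c("pre", "interview", "post")
  if (!identical(names(durations), ph))
    stop("durations must be named pre, interview, post", call. = FALSE)
  if (any(durations <= 0)) stop("phase durations must be positive", call. = FALSE)
  if (is.null(modulators)) {
    mean_rr <- c(pre = 680, interview = 586, post = 708)
    lf_pow  <- c(pre = 643, interview = 449, post = 1088)
    hf_pow  <- c(pre = 295, interview = 232, post = 373)
    modulators <- lapply(ph, function(p)
      modulator_spec(mean_rr = mean_rr[[p]],
                     lf_amp = sqrt(2 * lf_pow[[p]]),
                     hf_amp = sqrt(2 * hf_pow[[p]]),
                     noise_sd = noise_sd))
    names(modulators) <- ph
  }
  if (!identical(names(modulators), ph) ||
      !all(vapply(modulators, inherits, TRUE, "modulator_spec")))
    stop("modulators must be a named list of three modulator_spec", call. = FALSE)
  structure(list(durations = durations, modulators = modulators),
            class = "protocol_config")
}

#' Simulate a three-phase RR recording
#'
#' Runs the IPFM generator phase by phase and concatenates the beats into a
#' single recording with contiguous phase annotations. Oscillator phases are
#' drawn uniformly per recording (so subjects are decorrelated) unless the
#' protocol's modulators are to be used verbatim.
#'
#' @param protocol a [protocol_config].
#' @param subject optional named list / one-row data.frame of subject
#'   metadata carried along (id, age, gender, ...).
#' @param seed optional integer seed; fixed seed gives identical recordings.
#' @param random_phases draw oscillator phases uniformly at random
#'   (default `TRUE`).
#' @return An `rr_recording`: list with elements `rr` ([rr_series]),
#'   `phases` (data.frame `phase,start_s,end_s`) and `meta`.
#' @export
simulate_recording <- function(protocol, subject = NULL, seed = NULL,
                               random_phases = TRUE) {
  stopifnot(inherits(protocol, "protocol_config"))
  if (!is.null(seed)) set.seed(seed)
  offset <- 0
  beats <- numeric(0)
  ann <- data.frame(phase = character(0), start_s = numeric(0),
                    end_s = numeric(0), stringsAsFactors = FALSE)
  for (p in names(protocol$durations)) {
    mod <- protocol$modulators[[p]]
    if (random_phases) {
      mod$lf_phase <- stats::runif(1, 0, 2 * pi)
      mod$hf_phase <- stats::runif(1, 0, 2 * pi)
    }
    dur <- protocol$durations[[p]]
    b <- ipfm_beat_times(mod, dur)
    beats <- c(beats, b + offset)
    ann <- rbind(ann, data.frame(phase = p, start_s = offset,
                                 end_s = offset + dur,
                                 stringsAsFactors = FALSE))
    offset <- offset + dur
  }
  intervals <- diff(c(0, beats)) * 1000
  structure(list(rr = rr_series(intervals, beat_times = beats),
                 phases = ann, meta = subject),
            class = "rr_recording")
}

#' @export
print.rr_recording <- function(x, ...) {
  cat(sprintf("<rr_recording> %d beats over %.0f s (%s)\n", x$rr$n,
              max(x$phases$end_s), paste(x$phases$phase, collapse = " > ")))
  invisible(x)
}

#' Artifact contamination rates
#'
#' Per-beat probabilities for the four artifact classes seen in chest-strap
#' RR exports. Defaults give a 3% total contamination, under the 5% quality
#' gate used downstream.
#'
#' @param ectopic premature beat with compensatory pause (one interval
#'   shortened, the next lengthened by the same amount).
#' @param missed an undetected beat: two adjacent intervals merged.
#' @param extra a spurious detection: one interval split in two.
#' @param misaligned a detection jittered in time: +/-50 ms antisymmetric
#'   shift on two adjacent intervals.
#' @return An `artifact_spec` object.
#' @export
artifact_spec <- function(ectopic = 0.010, missed = 0.0075, extra = 0.0075,
                          misaligned = 0.005) {
  rates <- c(ectopic = ectopic, missed = missed, extra = extra,
             misaligned = misaligned)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (sum(rates) >= 0.05)
    stop("total artifact rate must be < 0.05", call. = FALSE)
  structure(list(rates = rates), class = "artifact_spec")
}

#' Inject labelled artifacts into an RR series
#'
#' Corrupts a clean RR series with the four canonical artifact classes and
#' returns the ground-truth positions, for validating detectors. Positions
#' are drawn without replacement at least 3 beats apart so corruptions never
#' overlap. Every corruption conserves total elapsed time exactly: merges and
#' splits redistribute the same milliseconds, ectopic/misaligned shifts are
#' antisymmetric on interval pairs.
#'
#' @param rr an [rr_series] with at least 50 beats.
#' @param spec an [artifact_spec].
#' @param seed optional integer seed.
#' @return List with `rr` (corrupted [rr_series]) and `truth`, a data.frame
#'   `index,category` indexing positions in the corrupted series.
#' @export
inject_artifacts <- function(rr, spec, seed = NULL) {
  stopifnot(inherits(rr, "rr_series"), inherits(spec, "artifact_spec"))
  if (rr$n < 50) stop("need at least 50 beats", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- rr$intervals
  n <- length(x)

  counts <- vapply(spec$rates, function(r) stats::rbinom(1L, n, r), 0L)
  total <- sum(counts)
  if (total == 0L)
    return(list(rr = rr, truth = data.frame(index = integer(0),
                                            category = character(0),
                                            stringsAsFactors = FALSE)))

  # choose mutually distant positions (>= 3 apart, away from the edges)
  cand <- sample(3:(n - 3L))
  pos <- integer(0)
  for (p in cand) {
    if (length(pos) == total) break
    if (all(abs(pos - p) >= 3L)) pos <- c(pos, p)
  }
  if (length(pos) < total) {
    total <- length(pos)
    counts <- pmin(counts, total) # degenerate, only for very short series
  }
  cat_vec <- rep(names(counts), counts)[seq_len(total)]
  ev <- data.frame(index = pos[seq_len(total)], category = cat_vec,
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$index, decreasing = TRUE), , drop = FALSE]

  for (r in seq_len(nrow(ev))) {
    i <- ev$index[r]
    switch(ev$category[r],
      ectopic = {
        d <- stats::runif(1, 0.25, 0.40) * x[i]
        x[i] <- x[i] - d
        x[i + 1L] <- x[i + 1L] + d
      },
      missed = {
        x[i] <- x[i] + x[i + 1L]
        x <- x[-(i + 1L)]
      },
      extra = {
        f <- stats::runif(1, 0.35, 0.65)
        v <- x[i]
        x <- append(x, (1 - f) * v, after = i)
        x[i] <- f * v
      },
      misaligned = {
        j <- 50 * sample(c(-1, 1), 1L)
        if (x[i] + j <= 50 || x[i + 1L] - j <= 50) j <- -j
        x[i] <- x[i] + j
        x[i + 1L] <- x[i + 1L] - j
      })
  }

  # map original positions to indices in the corrupted series
  ev <- ev[order(ev$index), , drop = FALSE]
  delta <- ifelse(ev$category == "missed", -1L,
                  ifelse(ev$category == "extra", 1L, 0L))
  shift_before <- c(0L, cumsum(delta))[seq_len(nrow(ev))]
  truth <- data.frame(index = ev$index + shift_before, category = ev$category,
                      stringsAsFactors = FALSE)
  list(rr = rr_series(x), truth = truth)
}
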