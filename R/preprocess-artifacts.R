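# rolling quartile deviation (IQR/2) over centered windows; evaluated on a
# stride and linearly interpolated between evaluation points
rolling_qd <- function(x, width = 91L, stride = 5L) {
  n <- length(x)
  half <- width %/% 2L
  at <- unique(c(seq(1L, n, by = stride), n))
  q7 <- function(xs, p) { # type-7 quantile of a sorted vector
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  qd <- vapply(at, function(i) {
    w <- sort(x[max(1L, i - half):min(n, i + half)], method = "quick")
    (q7(w, 0.75) - q7(w, 0.25)) / 2
  }, 0)
  if (length(at) == 1L) return(rep(qd, n))
  stats::approx(at, qd, xout = seq_len(n))$y
}

# replace the interval pair (i, i+1) by spline-interpolated values rescaled
# to the original pair sum, so elapsed time is conserved exactly
interp_pair <- function(x, i, exclude) {
  n <- length(x)
  idx <- setdiff(max(1L, i - 6L):min(n, i + 7L), exclude)
  idx <- idx[idx != i & idx != i + 1L]
  if (length(idx) < 2L) return(x)
  v <- stats::spline(idx, x[idx], xout = c(i, i + 1L), method = "fmm")$y
  v <- pmax(v, 0.1 * stats::median(x[idx]))
  s <- (x[i] + x[i + 1L]) / sum(v)
  x[c(i, i + 1L)] <- v * s
  x
}

#' Detect and correct RR artifacts
#'
#' Flags suspect beats with adaptive, quartile-deviation-scaled thresholds on
#' the successive-difference series (dRR) and on deviations from a running
#' local median (mRR): beat *i* is suspect when `|dRR_i|` or `|mRR_i|`
#' exceeds `threshold` times the local quartile deviation of the respective
#' series (windows of `qd_window` beats, truncated at the edges). Suspects
#' are then classified and corrected:
#'
#' * **missed** — the interval is about twice the local median (ratio within
#'   1.7-2.3): split into two equal halves;
#' * **extra** — the interval plus its successor is about one local median
#'   (ratio within 0.7-1.3): the pair is merged;
#' * **ectopic** — a short/long (or long/short) antisymmetric alternation:
#'   the pair is replaced by spline-interpolated values rescaled to the
#'   original pair sum;
#' * **misaligned** — any remaining suspect: corrected like an ectopic pair
#'   with the better-cancelling neighbour.
#'
#' All corrections conserve total elapsed time exactly. A warning is raised
#' when the percentage of corrected beats reaches 5%, the conventional
#' quality gate for short-term HRV recordings.
#'
#' @param rr an [rr_series] with at least 20 beats.
#' @param threshold multiplier on the quartile deviation (default 5.2).
#' @param qd_window window for the quartile deviation, beats (default 91).
#' @param median_window window for the running median, beats (odd, default 11).
#' @param qd_stride stride at which the quartile deviation is evaluated
#'   before linear interpolation (default 5; 1 evaluates every beat).
#' @return List with `rr`, the corrected [rr_series], and `labels`, an
#'   `artifact_labels` object: per-beat `category` on the *input* series
#'   (`normal`, `ectopic`, `missed`, `extra`, `misaligned`; pair corrections
#'   mark both beats), `corrected_pct` (corrections per 100 input beats) and
#'   `n_corrected` (number of corrections applied).
#' @export
detect_and_correct_artifacts <- function(rr, threshold = 5.2,
                                         qd_window = 91L,
                                         median_window = 11L,
                                         qd_stride = 5L) {
  stopifnot(inherits(rr, "rr_series"))
  if (rr$n < 20L) stop("need at least 20 beats", call. = FALSE)
  x <- rr$intervals
  n <- length(x)
  if (any(x <= 0)) stop("non-positive RR interval", call. = FALSE)

  med <- stats::runmed(x, median_window, endrule = "median")
  drr <- c(0, diff(x))
  mrr <- x - med
  th_d <- threshold * rolling_qd(drr, qd_window, qd_stride)
  th_m <- threshold * rolling_qd(mrr, qd_window, qd_stride)
  suspect <- abs(drr) > th_d | abs(mrr) > th_m

  consumed <- rep(FALSE, n)
  plan <- list()
  # a correction at (i, i+1) leaves an expected dRR echo on the next beat;
  # a trailing suspect that deviates in dRR only is part of the same event
  consume_echo <- function(j) {
    if (j <= n && suspect[j] && abs(mrr[j]) <= th_m[j]) consumed[j] <<- TRUE
  }
  for (i in which(suspect)) {
    if (consumed[i]) next
    m_i <- med[i]
    type <- NULL
    if (x[i] / m_i >= 1.7 && x[i] / m_i <= 2.3) {
      type <- "missed"
    } else if (i < n) {
      pair_ratio <- (x[i] + x[i + 1L]) / m_i
      dev_i <- x[i] - m_i
      dev_n <- x[i + 1L] - med[i + 1L]
      if (pair_ratio >= 0.7 && pair_ratio <= 1.3) {
        type <- "extra"
      } else if (dev_i * dev_n < 0 &&
                 abs(dev_i + dev_n) < 0.5 * max(abs(dev_i), abs(dev_n))) {
        type <- "ectopic"
      }
    }
    if (is.null(type)) type <- "misaligned"
    j <- i
    if (type == "misaligned") {
      # a time-shifted detection perturbs two adjacent intervals
      # antisymmetrically: correct only when a neighbour's deviation
      # cancels this one's, otherwise the excursion is genuine rhythm
      dev_i <- x[i] - m_i
      cand <- c(if (i > 1L && !consumed[i - 1L]) i - 1L, if (i < n) i + 1L)
      if (length(cand) == 0L) next
      resid <- abs(dev_i + (x[cand] - med[cand]))
      best <- which.min(resid)
      if (resid[best] >= 0.7 * max(abs(dev_i), abs(x[cand[best]] - med[cand[best]]))) {
        consumed[i] <- TRUE # suspect without artifact structure: leave as is
        next
      }
      j <- min(max(cand[best], 1L), n - 1L)
      if (j == i) j <- max(i - 1L, 1L)
      # store the lower index of the pair
      pr <- min(i, j)
      plan[[length(plan) + 1L]] <- list(type = type, index = pr)
      consumed[pr:(pr + 1L)] <- TRUE
      consume_echo(pr + 2L)
      next
    }
    plan[[length(plan) + 1L]] <- list(type = type, index = i)
    consumed[i] <- TRUE
    if (type == "missed") consume_echo(i + 1L)
    if (type %in% c("extra", "ectopic") && i < n) {
      consumed[i + 1L] <- TRUE
      consume_echo(i + 2L)
    }
  }

  # per-beat categories on the INPUT series (comparable to ground truth)
  labels <- rep("normal", n)
  if (length(plan)) {
    for (k in seq_along(plan)) {
      i <- plan[[k]]$index
      type <- plan[[k]]$type
      labels[i] <- type
      if (type != "missed" && i < n) labels[i + 1L] <- type
    }
    ord <- order(vapply(plan, `[[`, 0L, "index"), decreasing = TRUE)
    suspect_idx <- which(suspect)
    for (k in ord) {
      i <- plan[[k]]$index
      switch(plan[[k]]$type,
        missed = {
          h <- x[i] / 2
          x <- append(x[-i], c(h, h), after = i - 1L)
        },
        extra = {
          x[i] <- x[i] + x[i + 1L]
          x <- x[-(i + 1L)]
        },
        ectopic = {
          x <- interp_pair(x, i, exclude = suspect_idx)
        },
        misaligned = {
          x <- interp_pair(x, i, exclude = suspect_idx)
        })
    }
  }

  n_corr <- length(plan)
  pct <- 100 * n_corr / n
  if (pct >= 5)
    warning(sprintf("corrected_pct %.1f%% reaches the 5%% quality gate", pct),
            call. = FALSE)
  out_rr <- rr_series(x)
  lab <- structure(list(category = labels, corrected_pct = pct,
                        n_corrected = n_corr),
                   class = "artifact_labels")
  list(rr = out_rr, labels = lab)
}

#' @export
print.artifact_labels <- function(x, ...) {
  cat(sprintf("<artifact_labels> %d corrected beats (%.2f%%)\n",
              x$n_corrected, x$corrected_pct))
  invisible(x)
}
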