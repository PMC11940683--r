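#' LHFP/LHFND plane transform
#'
#' Maps LF/HF band powers to the bidimensional autonomic-balance coordinates:
#' the combined oscillatory power `lhfp = lf + hf` (ms^2) and the bounded,
#' symmetric balance index `lhfnd = (lf - hf)/(lf + hf)` in `[-1, 1]`.
#' Geometrically this is a normalized 45-degree rotation of the HF-LF plane;
#' unlike the LF/HF ratio the balance coordinate is not distorted by extreme
#' values. `from_bidim()` is the exact inverse:
#' `lf = lhfp (1 + lhfnd)/2`, `hf = lhfp (1 - lhfnd)/2`.
#'
#' @param lf,hf band powers, ms^2 (non-negative, `lf + hf > 0`). Vectorized.
#' @param lhfp combined power, ms^2 (> 0). Vectorized.
#' @param lhfnd balance index in `[-1, 1]`.
#' @return `to_bidim()`: list with `lhfp`, `lhfnd`; `from_bidim()`: list with
#'   `lf`, `hf`.
#' @examples
#' to_bidim(643, 295) # lhfp 938
#' @export
to_bidim <- function(lf, hf) {
  if (any(lf < 0) || any(hf < 0))
    stop("lf and hf must be non-negative", call. = FALSE)
  if (any(lf + hf == 0))
    stop("lhfnd undefined: lf + hf = 0", call. = FALSE)
  list(lhfp = lf + hf, lhfnd = (lf - hf) / (lf + hf))
}

#' @rdname to_bidim
#' @export
from_bidim <- function(lhfp, lhfnd) {
  if (any(lhfp <= 0)) stop("lhfp must be positive", call. = FALSE)
  if (any(abs(lhfnd) > 1)) stop("|lhfnd| must be <= 1", call. = FALSE)
  list(lf = lhfp * (1 + lhfnd) / 2, hf = lhfp * (1 - lhfnd) / 2)
}

#' Group-by-phase trajectories in both planes
#'
#' Averages per-subject feature rows into group x phase centroids in the
#' HF-LF plane and the LHFP-LHFND plane. The LHFND centroid is the mean of
#' the per-subject balance indices, not the balance of the mean powers (the
#' two differ whenever power varies across subjects).
#'
#' @param features a [compute_feature_table()] data.frame (columns `subject`,
#'   `phase`, `lf`, `hf`, `lhfp`, `lhfnd`).
#' @param grouping either a column name present in `features`, or a named
#'   vector/data.frame mapping `subject` to a group label; omit for a single
#'   group.
#' @return data.frame `group, phase, n, lf, hf, lhfp, lhfnd` (means over
#'   subjects), phases in recording order.
#' @export
phase_trajectory <- function(features, grouping = NULL) {
  df <- features[!is.na(features$lf), , drop = FALSE]
  if (is.null(grouping)) {
    df$group <- "all"
  } else if (is.character(grouping) && length(grouping) == 1L &&
             grouping %in% names(df)) {
    df$group <- df[[grouping]]
  } else if (is.data.frame(grouping)) {
    stopifnot(all(c("subject", "group") %in% names(grouping)))
    df$group <- grouping$group[match(df$subject, grouping$subject)]
  } else {
    df$group <- unname(grouping[df$subject])
  }
  if (anyNA(df$group)) stop("unmapped subjects in grouping", call. = FALSE)
  phases <- unique(features$phase)
  out <- expand.grid(group = unique(df$group), phase = phases,
                     stringsAsFactors = FALSE)
  agg <- function(col, g, p) {
    v <- df[[col]][df$group == g & df$phase == p]
    if (length(v) == 0L) stop("empty group x phase cell: ", g, " / ", p,
                              call. = FALSE)
    mean(v)
  }
  out$n <- mapply(function(g, p) sum(df$group == g & df$phase == p),
                  out$group, out$phase)
  for (col in c("lf", "hf", "lhfp", "lhfnd"))
    out[[col]] <- mapply(function(g, p) agg(col, g, p), out$group, out$phase)
  out
}

#' Qualitative autonomic state relative to a baseline
#'
#' Classifies a point in the HF-LF plane against a baseline using the
#' interpretive vocabulary of bidimensional autonomic analysis. LF and HF are
#' each rated high/neutral/low with a `dead_zone` fractional band around the
#' baseline (default +/-20%), then mapped:
#'
#' * high LF, low HF — `physical_stress` (the upper-left quadrant);
#' * low LF, low HF — `emotional_stress` (lower-left);
#' * high LF, high HF — `recovery_rebound` (upper-right, first recovery);
#' * both neutral, or HF at/above baseline with LF not elevated — `rest`;
#' * neutral LF with moderately low HF (ratio in `[flow_floor, 1 - dead_zone)`)
#'   — `flow` (engaged, moderate activation);
#' * neutral LF with strongly suppressed HF (ratio `< flow_floor`) —
#'   `mental_stress`;
#' * a single elevated/suppressed LF with neutral HF falls to
#'   `physical_stress` / `emotional_stress` by its LF side.
#'
#' The rule only uses power *ratios*, so it is invariant to rescaling both
#' point and baseline.
#'
#' @param point,baseline lists/rows with `lf` and `hf` (ms^2); baseline
#'   powers must be positive.
#' @param dead_zone fractional half-width of the neutral band (default 0.2).
#' @param flow_floor lower HF ratio bound of the `flow` band (default 0.5).
#' @return A character scalar state label with attribute `ratios`.
#' @export
classify_state <- function(point, baseline, dead_zone = 0.2,
                           flow_floor = 0.5) {
  if (baseline$lf <= 0 || baseline$hf <= 0)
    stop("baseline powers must be positive", call. = FALSE)
  rl <- point$lf / baseline$lf
  rh <- point$hf / baseline$hf
  lev <- function(r) if (r > 1 + dead_zone) "high" else
    if (r < 1 - dead_zone) "low" else "neutral"
  L <- lev(rl); H <- lev(rh)
  label <-
    if (L == "high" && H == "low") "physical_stress"
    else if (L == "low" && H == "low") "emotional_stress"
    else if (L == "high" && H == "high") "recovery_rebound"
    else if (L == "neutral" && H == "low")
      (if (rh >= flow_floor) "flow" else "mental_stress")
    else if (H == "high") "rest"              # vagal-dominant, not rebounding
    else if (L == "high") "physical_stress"   # high LF, neutral HF
    else if (L == "low") "emotional_stress"   # low LF, neutral HF
    else "rest"                               # both neutral
  structure(label, ratios = c(lf = rl, hf = rh))
}
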