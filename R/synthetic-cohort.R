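#' Cohort simulator configuration
#'
#' Describes a cohort of communicators whose autonomic trajectories differ by
#' performance cluster: *low*-Authority subjects show a marked LF power drop
#' from baseline into the stressor and a strong post-stress rebound, while
#' *high*-Authority subjects stay near-constant ("flow"). Default per-phase
#' targets are calibrated to published group values: LF 900/208/1552 ms^2 for
#' the low cluster (pre-to-interview difference -692 ms^2, interview-to-post
#' +1344 ms^2) and a flat 643 ms^2 for the high cluster; HF 295/232/373 ms^2
#' and mean RR around 680/586/708 ms for both.
#'
#' @param n_subjects number of subjects (>= 6, default 24).
#' @param cluster_fractions named fractions for `low` and `high` clusters,
#'   summing to 1.
#' @param lf_targets named list (`low`, `high`) of per-phase LF power targets
#'   in ms^2 (`pre`, `interview`, `post`).
#' @param hf_targets per-phase HF power targets, ms^2 (shared by clusters).
#' @param rr_targets named list of per-phase mean RR targets, ms.
#' @param age_mean,age_sd,log_pub_mean,log_pub_sd covariate distributions
#'   (natural-log publication count).
#' @param gender_ratio probability of `F`.
#' @param subject_sdlog log-normal sd of the per-subject amplitude
#'   multiplier (shared across phases, so within-subject patterns persist).
#' @param phase_sdlog additional per-phase log-normal jitter.
#' @param rr_jitter_sd between-subject sd of the mean-RR offset, ms.
#' @param noise_sd broadband modulator noise, ms.
#' @param durations phase durations, s.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_subjects = 24,
                          cluster_fractions = c(low = 0.5, high = 0.5),
                          lf_targets = list(
                            low  = c(pre = 900, interview = 208, post = 1552),
                            high = c(pre = 643, interview = 643, post = 643)),
                          hf_targets = c(pre = 295, interview = 232, post = 373),
                          rr_targets = list(
                            low  = c(pre = 680, interview = 570, post = 708),
                            high = c(pre = 680, interview = 600, post = 708)),
                          age_mean = 52.64, age_sd = 9,
                          log_pub_mean = 3.9231, log_pub_sd = 0.9,
                          gender_ratio = 0.5,
                          subject_sdlog = 0.20, phase_sdlog = 0.05,
                          rr_jitter_sd = 30, noise_sd = 10,
                          durations = c(pre = 300, interview = 600, post = 300)) {
  if (n_subjects < 6) stop("n_subjects must be >= 6", call. = FALSE)
  if (!identical(sort(names(cluster_fractions)), c("high", "low")) ||
      abs(sum(cluster_fractions) - 1) > 1e-9 || any(cluster_fractions <= 0))
    stop("cluster_fractions must be positive, named low/high, and sum to 1",
         call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 cluster_fractions = cluster_fractions,
                 lf_targets = lf_targets, hf_targets = hf_targets,
                 rr_targets = rr_targets,
                 age_mean = age_mean, age_sd = age_sd,
                 log_pub_mean = log_pub_mean, log_pub_sd = log_pub_sd,
                 gender_ratio = gender_ratio,
                 subject_sdlog = subject_sdlog, phase_sdlog = phase_sdlog,
                 rr_jitter_sd = rr_jitter_sd, noise_sd = noise_sd,
                 durations = durations),
            class = "cohort_config")
}

#' Simulate a cohort of three-phase recordings
#'
#' Draws covariates and cluster membership, builds per-subject phase
#' modulators around the cluster targets, and simulates each recording with
#' the IPFM generator. Cluster membership is recorded as ground truth.
#'
#' @param cfg a [cohort_config].
#' @param seed optional integer seed.
#' @return List with `recordings` (named list of `rr_recording`) and
#'   `cohort`, a data.frame `subject_id,age,gender,log_pub,cluster`.
#' @export
simulate_cohort <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_subjects
  n_low <- round(cfg$cluster_fractions[["low"]] * n)
  cluster <- c(rep("low", n_low), rep("high", n - n_low))
  ids <- sprintf("S%02d", seq_len(n))
  cohort <- data.frame(
    subject_id = ids,
    age = stats::rnorm(n, cfg$age_mean, cfg$age_sd),
    gender = ifelse(stats::runif(n) < cfg$gender_ratio, "F", "M"),
    log_pub = stats::rnorm(n, cfg$log_pub_mean, cfg$log_pub_sd),
    cluster = cluster,
    stringsAsFactors = FALSE)

  phases <- c("pre", "interview", "post")
  recordings <- vector("list", n)
  names(recordings) <- ids
  for (s in seq_len(n)) {
    cl <- cluster[s]
    amp_mult <- exp(stats::rnorm(1, 0, cfg$subject_sdlog))
    rr_off <- stats::rnorm(1, 0, cfg$rr_jitter_sd)
    mods <- lapply(phases, function(p) {
      ph_mult <- exp(stats::rnorm(1, 0, cfg$phase_sdlog))
      modulator_spec(
        mean_rr = cfg$rr_targets[[cl]][[p]] + rr_off,
        lf_amp = sqrt(2 * cfg$lf_targets[[cl]][[p]]) * amp_mult * ph_mult,
        hf_amp = sqrt(2 * cfg$hf_targets[[p]]) * amp_mult * ph_mult,
        noise_sd = cfg$noise_sd)
    })
    names(mods) <- phases
    proto <- protocol_config(durations = cfg$durations, modulators = mods)
    rec <- simulate_recording(proto, subject = list(id = ids[s], cluster = cl))
    recordings[[s]] <- rec
  }
  list(recordings = recordings, cohort = cohort)
}

#' Write a simulated cohort to disk
#'
#' Emits the file set the pipeline reads back: one plain-text RR file and one
#' phase-annotation CSV per subject, plus the cohort covariate table.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(sim$recordings)) {
    rec <- sim$recordings[[id]]
    write_rr(rec$rr, file.path(dir, paste0(id, "_rr.txt")))
    utils::write.csv(rec$phases, file.path(dir, paste0(id, "_phases.csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
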