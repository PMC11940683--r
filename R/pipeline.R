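#' Pipeline configuration
#'
#' Bundles every tunable analysis setting with the conventional defaults:
#' 0.003-0.04 / 0.04-0.15 / 0.15-0.40 Hz bands, smoothness-priors
#' `lambda = 500`, 4 Hz resampling, 300 s Welch windows with 50% overlap,
#' 300 s preferred / 180 s fallback segments, the adaptive artifact-rule
#' constants, the +/-20% classification dead zone, eigenvalue > 1 component
#' retention and Bonferroni-adjusted contrasts.
#'
#' @param bands band edges, Hz (`vlf_lo, vlf_hi, lf_hi, hf_hi`).
#' @param lam detrending smoothing parameter.
#' @param sample_rate tachogram rate, Hz.
#' @param window_s,overlap Welch settings.
#' @param preferred_s,fallback_s segment policy, s.
#' @param artifact_threshold,qd_window,median_window artifact-rule constants.
#' @param dead_zone state-classification dead zone, fraction.
#' @param adjust pairwise multiplicity rule.
#' @param seed integer seed recorded in the run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bands = c(0.003, 0.04, 0.15, 0.40), lam = 500,
                            sample_rate = 4, window_s = 300, overlap = 0.5,
                            preferred_s = 300, fallback_s = 180,
                            artifact_threshold = 5.2, qd_window = 91L,
                            median_window = 11L, dead_zone = 0.2,
                            adjust = "bonferroni", seed = 1L) {
  stopifnot(all(diff(bands) > 0), all(bands > 0), lam >= 0, sample_rate > 0,
            window_s > 0, overlap >= 0, overlap < 1,
            preferred_s >= fallback_s, fallback_s > 0)
  structure(list(bands = bands, lam = lam, sample_rate = sample_rate,
                 window_s = window_s, overlap = overlap,
                 preferred_s = preferred_s, fallback_s = fallback_s,
                 artifact_threshold = artifact_threshold,
                 qd_window = qd_window, median_window = median_window,
                 dead_zone = dead_zone, adjust = adjust, seed = seed),
            class = "pipeline_config")
}

#' Read a cohort of recordings from disk
#'
#' Loads the file set written by [write_cohort()]: `cohort.csv` plus one
#' `<id>_rr.txt` and `<id>_phases.csv` per subject.
#'
#' @param dir input directory.
#' @return List with `recordings` and `cohort` as in [simulate_cohort()].
#' @export
read_cohort <- function(dir) {
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  recordings <- lapply(cohort$subject_id, function(id) {
    rr <- read_rr(file.path(dir, paste0(id, "_rr.txt")))
    phases <- utils::read.csv(file.path(dir, paste0(id, "_phases.csv")),
                              stringsAsFactors = FALSE)
    structure(list(rr = rr, phases = phases, meta = list(id = id)),
              class = "rr_recording")
  })
  names(recordings) <- cohort$subject_id
  list(recordings = recordings, cohort = cohort)
}

#' Run the full analysis pipeline
#'
#' Preprocess -> features -> bidimensional trajectories -> statistics, over
#' a cohort of recordings. Per-subject failures are recorded in the log and
#' do not stop the run. When `output_dir` is given, the feature table,
#' trajectories, ANOVA tables, contrasts, log and a JSON run manifest are
#' written there.
#'
#' @param cohort list with `recordings` and `cohort` (from
#'   [simulate_cohort()] or [read_cohort()]).
#' @param config a [pipeline_config()].
#' @param dvs dependent variables to analyse (default
#'   `c("lf", "hf", "lhfp", "lhfnd", "mean_rr")`).
#' @param output_dir optional output directory.
#' @return List with `features`, `trajectory`, `anova` (named list of tidy
#'   tables), `contrasts` (named list), and `log` (subject, phase, status).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         dvs = c("lf", "hf", "lhfp", "lhfnd", "mean_rr"),
                         output_dir = NULL) {
  feats <- compute_feature_table(
    cohort$recordings, lam = config$lam, sample_rate = config$sample_rate,
    window_s = config$window_s, overlap = config$overlap,
    preferred_s = config$preferred_s, fallback_s = config$fallback_s,
    bands = config$bands)

  log_df <- data.frame(subject = feats$subject, phase = feats$phase,
                       status = ifelse(feats$flags == "", "ok", feats$flags),
                       stringsAsFactors = FALSE)

  have_cluster <- "cluster" %in% names(cohort$cohort)
  grouping <- if (have_cluster)
    data.frame(subject = cohort$cohort$subject_id,
               group = cohort$cohort$cluster, stringsAsFactors = FALSE)
  traj <- phase_trajectory(feats, if (have_cluster) grouping else NULL)

  # statistics on complete, non-excluded subjects
  ok <- feats[!is.na(feats$lf) & !grepl("excluded", feats$flags), ]
  n_phase <- length(unique(feats$phase))
  complete <- names(which(table(ok$subject) == n_phase))
  ok <- ok[ok$subject %in% complete, ]
  meta_cols <- intersect(c("cluster", "gender", "age", "log_pub"),
                         names(cohort$cohort))
  stat_dat <- merge(ok, cohort$cohort[, c("subject_id", meta_cols)],
                    by.x = "subject", by.y = "subject_id")
  between <- intersect(c("cluster", "gender"), meta_cols)
  covars <- intersect(c("age", "log_pub"), meta_cols)
  anova_tabs <- list()
  contrast_tabs <- list()
  for (dv in dvs) {
    fit <- tryCatch(
      rm_anova(stat_dat, dv, between = between, covariates = covars),
      error = function(e) e)
    if (inherits(fit, "error")) {
      anova_tabs[[dv]] <- conditionMessage(fit)
      next
    }
    anova_tabs[[dv]] <- fit$table
    contrast_tabs[[dv]] <- adjusted_pairwise_contrasts(
      fit, adjust = config$adjust)$contrasts
  }

  res <- list(features = feats, trajectory = traj, anova = anova_tabs,
              contrasts = contrast_tabs, log = log_df)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(feats, file.path(output_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(traj, file.path(output_dir, "trajectory.csv"),
                     row.names = FALSE)
    stat_rows <- do.call(rbind, lapply(names(anova_tabs), function(dv) {
      tb <- anova_tabs[[dv]]
      if (!is.data.frame(tb)) return(NULL)
      cbind(dv = dv, tb)
    }))
    if (!is.null(stat_rows))
      utils::write.csv(stat_rows, file.path(output_dir, "anova.csv"),
                       row.names = FALSE)
    ctr_rows <- do.call(rbind, lapply(names(contrast_tabs), function(dv)
      cbind(dv = dv, contrast_tabs[[dv]])))
    if (!is.null(ctr_rows))
      utils::write.csv(ctr_rows, file.path(output_dir, "contrasts.csv"),
                       row.names = FALSE)
    utils::write.csv(log_df, file.path(output_dir, "log.csv"),
                     row.names = FALSE)
    manifest <- list(seed = config$seed,
                     config = unclass(config),
                     n_subjects = length(cohort$recordings),
                     excluded = log_df[log_df$status != "ok", ])
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
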