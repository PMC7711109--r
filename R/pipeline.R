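#' Pipeline configuration
#'
#' Collects every tunable of the synthetic end-to-end pipeline, validated at
#' construction and serialized verbatim into the run manifest. All
#' randomness flows from `seed`, split deterministically per subject and
#' stage.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param n_voxels Voxels per subject.
#' @param n_blocks Task blocks (>= 2 for cross-validation).
#' @param per_condition_block_seconds Stimulus seconds per condition per
#'   block.
#' @param trial_bounds Stimulus trial duration range (s).
#' @param meditation_duration_trs Meditation length in TRs.
#' @param noise_sd Gaussian noise SD of the simulator.
#' @param amplitude,sparsity,overlap Pattern generator settings, see
#'   [make_state_patterns()].
#' @param stationary Planted meditation stationary distribution over
#'   (Breath, MW, Self).
#' @param mean_dwell Resampling time scale of the meditation chain (TRs).
#' @param penalty,chance_level Classifier settings, see
#'   [classifier_config()].
#' @param k_sd Importance threshold multiplier.
#' @param min_event_len Minimum mental-event length (TRs).
#' @param lag_trs Hemodynamic lag applied when labeling TRs.
#' @param tr_seconds TR duration (s).
#' @param seed Root seed.
#' @return Object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(n_subjects = 5L, n_voxels = 200L, n_blocks = 6L,
                            per_condition_block_seconds = 72,
                            trial_bounds = c(16, 50),
                            meditation_duration_trs = 600L, noise_sd = 1,
                            amplitude = 1, sparsity = 0.1, overlap = 0,
                            stationary = c(0.5, 0.3, 0.2), mean_dwell = 10,
                            penalty = 0.01, chance_level = 0.2, k_sd = 2,
                            min_event_len = 3L, lag_trs = 0L, tr_seconds = 1,
                            seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_voxels = as.integer(n_voxels), n_blocks = as.integer(n_blocks),
              per_condition_block_seconds = per_condition_block_seconds,
              trial_bounds = trial_bounds,
              meditation_duration_trs = as.integer(meditation_duration_trs),
              noise_sd = noise_sd, amplitude = amplitude, sparsity = sparsity,
              overlap = overlap, stationary = stationary,
              mean_dwell = mean_dwell, penalty = penalty,
              chance_level = chance_level, k_sd = k_sd,
              min_event_len = as.integer(min_event_len),
              lag_trs = as.integer(lag_trs), tr_seconds = tr_seconds,
              seed = as.integer(seed))
  stopifnot(cfg$n_subjects >= 1L, cfg$n_voxels >= 5L,
            cfg$meditation_duration_trs >= 1L, cfg$noise_sd >= 0,
            cfg$min_event_len >= 1L, cfg$lag_trs >= 0L)
  classifier_config(cfg$penalty, cfg$chance_level)  # validates both
  if (length(cfg$stationary) != 3L || abs(sum(cfg$stationary) - 1) > 1e-9)
    stop("stationary must be a length-3 probability vector", call. = FALSE)
  # fail fast on infeasible designs and chain parameters
  feas <- feasible_partitions(cfg$per_condition_block_seconds,
                              cfg$trial_bounds)
  if (length(feas) == 0L)
    stop("trial_bounds cannot partition per_condition_block_seconds",
         call. = FALSE)
  stationary_transition_matrix(cfg$stationary, cfg$mean_dwell)
  structure(cfg, class = "pipeline_config")
}

#' Run one synthetic subject end to end
#'
#' Simulate a subject's patterns, IA session and meditation period, train and
#' cross-validate the state classifier, compute thresholded importance maps
#' for the meditation-relevant states, decode the meditation period, segment
#' mental events, and compute attention metrics.
#'
#' @param config A [pipeline_config()].
#' @param subject_index 1-based subject number (drives seed derivation).
#' @return List with `subject_id`, `patterns`, `design`, `samples`,
#'   `report`, `classifier`, `importance` (named list of thresholded maps),
#'   `decoded`, `events`, `metrics`, `truth`, `recovery`.
#' @export
run_subject <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  sid <- sprintf("sub-%02d", subject_index)
  seed0 <- derive_seed(config$seed, subject_index)
  patterns <- make_state_patterns(config$n_voxels, overlap = config$overlap,
                                  amplitude = config$amplitude,
                                  sparsity = config$sparsity,
                                  seed = derive_seed(seed0, 1L))
  design <- build_ia_design(
    n_blocks = config$n_blocks,
    per_condition_block_seconds = config$per_condition_block_seconds,
    trial_bounds = config$trial_bounds,
    order_set_id = (subject_index - 1L) %% 4L + 1L,
    tr_seconds = config$tr_seconds, seed = derive_seed(seed0, 2L))
  sess <- simulate_ia_session(patterns, design, noise_sd = config$noise_sd,
                              seed = derive_seed(seed0, 3L))
  sess$ts$subject_id <- sid
  samples <- extract_labeled_samples(sess$ts, sess$design,
                                     lag_trs = config$lag_trs)
  ccfg <- classifier_config(config$penalty, config$chance_level)
  report <- crossvalidate_by_block(samples, ccfg)
  classifier <- train_state_classifier(samples, ccfg)
  importance <- lapply(meditation_states(), function(s)
    threshold_importance(compute_importance_map(classifier, samples, s),
                         k_sd = config$k_sd))
  names(importance) <- meditation_states()
  P <- stationary_transition_matrix(config$stationary, config$mean_dwell)
  med <- simulate_meditation_session(
    patterns, P, duration_trs = config$meditation_duration_trs,
    noise_sd = config$noise_sd, seed = derive_seed(seed0, 4L),
    tr_seconds = config$tr_seconds)
  decoded <- decode_meditation(classifier, med$ts)
  events <- segment_mental_events(decoded, min_len = config$min_event_len)
  metrics <- compute_attention_metrics(decoded, events, subject_id = sid)
  list(subject_id = sid, patterns = patterns, design = sess$design,
       samples = samples, report = report, classifier = classifier,
       importance = importance, decoded = decoded, events = events,
       metrics = metrics, truth = med$truth,
       recovery = sequence_recovery_score(decoded, med$truth))
}

#' Run the full synthetic pipeline and write a report directory
#'
#' Executes simulate -> classifier training/cross-validation -> importance
#' maps -> meditation decoding -> attention metrics -> group statistics for
#' a synthetic cohort, writing per-subject and group tables plus a manifest
#' under `out_dir`. Identical configurations (including seed) produce
#' byte-identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; must be empty unless `force`.
#' @param force Overwrite files in a non-empty directory.
#' @return Invisibly, a list with `accuracy` (per subject x condition),
#'   `metrics` (stacked attention metrics), `group` (list of `group_stats`),
#'   `frequency` (per-state frequency maps), `recovery` (per-subject truth
#'   agreement), and `files` (paths written).
#' @export
run_full_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop("output directory ", out_dir,
         " is not empty; pass force = TRUE to overwrite", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    message(sprintf("[pipeline] subject %d/%d", i, config$n_subjects))
    run_subject(config, i)
  })
  states <- attention_states()
  accuracy <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id, condition = states,
               accuracy = as.numeric(s$report$per_condition_accuracy[states]),
               chisq = as.numeric(s$report$per_condition_chisq[states]),
               p = as.numeric(s$report$per_condition_chisq_p[states]),
               n = as.numeric(s$report$n_per_condition[states]),
               eligible = s$report$eligible)
  }))
  metrics <- do.call(rbind, lapply(subjects, `[[`, "metrics"))
  recovery <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    truth_agreement = vapply(subjects, `[[`, 0, "recovery"))
  group <- list()
  if (config$n_subjects >= 2L) {
    for (s in states) {
      vals <- 100 * accuracy$accuracy[accuracy$condition == s]
      if (stats::sd(vals) > 0)
        group[[paste0("accuracy_", s)]] <-
          group_accuracy_ttest(vals, 100 * config$chance_level)
    }
    for (other in c("MW", "Self")) {
      gs <- try(compare_breath_vs_other(metrics, other), silent = TRUE)
      if (!inherits(gs, "try-error"))
        group[[paste0("breath_vs_", other)]] <- gs
    }
  }
  frequency <- lapply(meditation_states(), function(s)
    importance_frequency_map(lapply(subjects, function(sub)
      sub$importance[[s]])))
  names(frequency) <- meditation_states()
  files <- write_reports(out_dir, config, subjects, accuracy, metrics,
                         group, frequency, recovery)
  invisible(list(accuracy = accuracy, metrics = metrics, group = group,
                 frequency = frequency, recovery = recovery, files = files))
}

#' Write pipeline report files
#'
#' Emits the numeric outputs of a completed run: per-subject accuracy and
#' attention-metric CSVs, decoded timelines and event TSVs, importance
#' frequency histograms, group statistics JSON, truth-agreement CSV, and a
#' manifest JSON recording the package version and full configuration.
#'
#' @param out_dir Destination directory (exists).
#' @param config,subjects,accuracy,metrics,group,frequency,recovery Artifacts
#'   produced by [run_full_pipeline()].
#' @return Named list of written paths.
#' @export
write_reports <- function(out_dir, config, subjects, accuracy, metrics,
                          group, frequency, recovery) {
  files <- list()
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  files$accuracy <- wcsv(accuracy, "accuracy.csv")
  files$metrics <- wcsv(metrics, "attention_metrics.csv")
  files$recovery <- wcsv(recovery, "truth_agreement.csv")
  for (sub in subjects) {
    dec <- data.frame(tr = seq_len(sub$decoded$n_trs) - 1L,
                      decision = as.character(sub$decoded$decisions),
                      round(sub$decoded$probabilities, 6))
    names(dec)[-(1:2)] <- paste0("p_", sub$decoded$state_set)
    files[[paste0("timeline_", sub$subject_id)]] <-
      wcsv(dec, sprintf("%s_timeline.csv", sub$subject_id))
    files[[paste0("events_", sub$subject_id)]] <-
      wcsv(as.data.frame(sub$events), sprintf("%s_events.csv",
                                              sub$subject_id))
    files[[paste0("confusion_", sub$subject_id)]] <-
      wcsv(as.data.frame(sub$report$confusion_matrix),
           sprintf("%s_confusion.csv", sub$subject_id))
  }
  hist_df <- do.call(rbind, lapply(names(frequency), function(s)
    cbind(state = s, frequency[[s]]$histogram)))
  files$frequency_histogram <- wcsv(hist_df, "frequency_histogram.csv")
  group_path <- file.path(out_dir, "group_stats.json")
  jsonlite::write_json(lapply(group, unclass), group_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files$group <- group_path
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest_path, list(config = unclass(config),
                                     n_subjects = length(subjects),
                                     outputs = lapply(files, basename)))
  files$manifest <- manifest_path
  files
}
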