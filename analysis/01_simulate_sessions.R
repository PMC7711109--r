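#!/usr/bin/env Rscript
# Stage 0: simulate the synthetic cohort.
#
# For each subject: state-specific voxel patterns, a randomized six-block
# internal-attention session (72 s per condition per block, 2-s instruction
# cues, trials of 16-50 s), and a 600-TR meditation period whose hidden
# state follows a Markov chain with planted stationary occupancy
# (Breath 50%, MW 30%, Self 20%). Sessions are written as NIfTI + events
# TSV (+ per-TR truth sidecar) under results/sessions/.

source(file.path("analysis", "00_settings.R"))

dir.create(SESSIONS, recursive = TRUE, showWarnings = FALSE)
P <- stationary_transition_matrix(COHORT$stationary, COHORT$mean_dwell)
summary_rows <- list()

for (i in seq_len(COHORT$n_subjects)) {
  sid <- subject_ids()[i]
  message("simulating ", sid)
  patterns <- subject_patterns(i)
  design <- build_ia_design(order_set_id = (i - 1L) %% 4L + 1L,
                            seed = subject_seed(i, 2L))
  ia <- simulate_ia_session(patterns, design, noise_sd = COHORT$noise_sd,
                            seed = subject_seed(i, 3L),
                            rating_coupling = 0)
  ia$ts$subject_id <- sid
  med <- simulate_meditation_session(
    patterns, P, duration_trs = COHORT$meditation_duration_trs,
    noise_sd = COHORT$noise_sd, seed = subject_seed(i, 4L))
  med$ts$subject_id <- sid

  d <- subject_dir(sid)
  write_session(ia$ts, ia$design, d, prefix = "ia")
  write_session(med$ts, NULL, d, truth = med$truth, prefix = "med")

  stim <- ia$design$trials[ia$design$trials$condition != "Instruction", ]
  summary_rows[[i]] <- data.frame(
    subject_id = sid, n_ia_trs = nrow(ia$ts$data),
    n_stimulus_trials = nrow(stim),
    stimulus_seconds = sum(stim$duration),
    meditation_trs = nrow(med$ts$data),
    true_pct_breath = 100 * mean(med$truth$state_sequence == "Breath"),
    true_pct_mw = 100 * mean(med$truth$state_sequence == "MW"),
    true_pct_self = 100 * mean(med$truth$state_sequence == "Self"))
}

tab <- do.call(rbind, summary_rows)
write.csv(tab, file.path(RESULTS, "cohort_sessions.csv"), row.names = FALSE)
message("\nCohort written. Each subject contributes ",
        tab$stimulus_seconds[1], " labeled stimulus seconds (",
        tab$stimulus_seconds[1] / 5, " s per condition) and ",
        tab$meditation_trs[1], " meditation TRs.")
print(tab, row.names = FALSE)
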