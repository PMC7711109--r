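# Shared settings for the analysis scripts: one synthetic cohort under the
# study's acquisition conditions (six IA blocks, 72 s per condition per
# block, TR = 1 s, 600-TR breath-meditation period), five subjects at 300
# voxels with unit noise. Scripts 01-06 each read/write under results/.

library(mindstates)

COHORT <- list(
  n_subjects = 5L,
  n_voxels = 300L,
  # per-TR noise is calibrated so that single-TR cross-validated accuracy
  # sits substantially above the 20% chance level but well below ceiling,
  # the regime in which TR-level fMRI decoding of internal attention
  # operates in practice
  noise_sd = 8,
  amplitude = 1,
  sparsity = 0.1,
  overlap = 0,
  stationary = c(0.5, 0.3, 0.2),   # planted Breath/MW/Self occupancy
  mean_dwell = 10,                  # chain resampling time scale (TRs)
  meditation_duration_trs = 600L,
  root_seed = 20260901L)

RESULTS <- "results"
SESSIONS <- file.path(RESULTS, "sessions")

subject_ids <- function() sprintf("sub-%02d", seq_len(COHORT$n_subjects))

subject_seed <- function(i, stage) {
  (COHORT$root_seed + i * 7919L + stage * 101L) %% 2000000000L
}

subject_dir <- function(sid) file.path(SESSIONS, sid)

# Rebuild a subject's generator state (patterns are needed by every stage;
# they are deterministic in the subject seed, so scripts stay independent).
subject_patterns <- function(i) {
  make_state_patterns(COHORT$n_voxels, overlap = COHORT$overlap,
                      amplitude = COHORT$amplitude,
                      sparsity = COHORT$sparsity,
                      seed = subject_seed(i, 1L))
}

load_subject_ia <- function(sid) {
  d <- subject_dir(sid)
  load_session(file.path(d, "ia_bold.nii.gz"),
               file.path(d, "ia_mask.nii.gz"),
               file.path(d, "ia_events.tsv"),
               tr_seconds = 1, subject_id = sid)
}

load_subject_meditation <- function(sid) {
  d <- subject_dir(sid)
  sess <- load_session(file.path(d, "med_bold.nii.gz"),
                       file.path(d, "med_mask.nii.gz"),
                       tr_seconds = 1, subject_id = sid)
  truth_tab <- read.delim(file.path(d, "med_truth.tsv"))
  P <- stationary_transition_matrix(COHORT$stationary, COHORT$mean_dwell)
  list(ts = sess$ts, truth = meditation_truth(truth_tab$state, P))
}
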