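#!/usr/bin/env Rscript
# Stage 2: TR-by-TR decoding of the meditation period.
#
# Each subject's classifier (retrained on their full internal-attention
# session) decodes the 600-TR meditation period: 5-class probabilities are
# restricted to Breath/MW/Self, renormalized, and decided by argmax. Mental
# events are maximal runs of >= 3 identical decisions. Since the sessions
# are synthetic, decisions are also scored against the hidden state
# sequence.

source(file.path("analysis", "00_settings.R"))

agree_rows <- list()
for (sid in subject_ids()) {
  message("decoding ", sid)
  ia <- load_subject_ia(sid)
  samples <- extract_labeled_samples(ia$ts, ia$design)
  clf <- train_state_classifier(samples)
  med <- load_subject_meditation(sid)
  decoded <- decode_meditation(clf, med$ts)
  events <- segment_mental_events(decoded, min_len = 3)

  timeline <- data.frame(tr = seq_len(decoded$n_trs) - 1L,
                         decision = as.character(decoded$decisions),
                         truth = as.character(med$truth$state_sequence),
                         round(decoded$probabilities, 6))
  names(timeline)[4:6] <- paste0("p_", decoded$state_set)
  write.table(timeline,
              file.path(subject_dir(sid), "decoded_timeline.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(events),
              file.path(subject_dir(sid), "mental_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  agree_rows[[sid]] <- data.frame(
    subject_id = sid, n_trs = decoded$n_trs,
    truth_agreement_pct =
      100 * sequence_recovery_score(decoded, med$truth),
    n_events = nrow(events),
    event_covered_pct = 100 * sum(events$duration_trs) / decoded$n_trs)
}

agree <- do.call(rbind, agree_rows)
write.csv(agree, file.path(RESULTS, "step2_decoding.csv"), row.names = FALSE)
message("\nDecoding summary:")
print(agree, row.names = FALSE)
message("Mean agreement with hidden truth: ",
        round(mean(agree$truth_agreement_pct), 1), "%")
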