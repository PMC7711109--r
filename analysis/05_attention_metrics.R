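#!/usr/bin/env Rscript
# Stage 3: individual attention metrics and group comparisons.
#
# Recomputes, from the decoded timelines of stage 2, each subject's
# attention profile: percentage time per state, number of mental events,
# mean and SD of event durations (s). Group level: paired t-tests of breath
# occupancy against MW and Self, and recovery of the planted (50/30/20)%
# occupancy.

source(file.path("analysis", "00_settings.R"))

metric_rows <- list()
for (sid in subject_ids()) {
  tl <- read.delim(file.path(subject_dir(sid), "decoded_timeline.tsv"))
  decoded <- structure(list(
    decisions = factor(tl$decision, levels = meditation_states()),
    probabilities = as.matrix(tl[, paste0("p_", meditation_states())]),
    n_trs = nrow(tl), state_set = meditation_states(), tr_seconds = 1),
    class = "decoded_session")
  metric_rows[[sid]] <- compute_attention_metrics(decoded, subject_id = sid)
}
metrics <- do.call(rbind, metric_rows)
write.csv(metrics, file.path(RESULTS, "step3_attention_metrics.csv"),
          row.names = FALSE)

group <- list(
  breath_vs_mw = unclass(compare_breath_vs_other(metrics, "MW")),
  breath_vs_self = unclass(compare_breath_vs_other(metrics, "Self")))
jsonlite::write_json(group, file.path(RESULTS, "step3_group_stats.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

mean_pct <- tapply(metrics$percent_time, metrics$state, mean)
message("Mean percentage time (planted 50/30/20):")
print(round(mean_pct[meditation_states()], 1))
message("Breath vs MW: t(", group$breath_vs_mw$df, ") = ",
        round(group$breath_vs_mw$t, 2), ", p = ",
        signif(group$breath_vs_mw$p, 3))
message("Breath vs Self: t(", group$breath_vs_self$df, ") = ",
        round(group$breath_vs_self$t, 2), ", p = ",
        signif(group$breath_vs_self$p, 3))
print(metrics, row.names = FALSE)
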