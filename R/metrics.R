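#' Per-subject attention metrics from a decoded meditation session
#'
#' Summarizes one decoded session per state (Breath, MW, Self): percentage of
#' meditation TRs decided as the state, number of mental events, and mean and
#' sample SD of event durations in seconds. Percentage time uses all decided
#' TRs (every TR receives a decision), not only TRs inside events; set
#' `events_only = TRUE` for the event-restricted alternative, where the
#' denominator stays the full session length so the three percentages then
#' sum to the event-covered fraction.
#'
#' @param decoded A [decode_meditation()] result.
#' @param events Events from [segment_mental_events()] on the same decisions;
#'   recomputed when omitted.
#' @param subject_id Label for the output rows.
#' @param events_only Restrict percent_time to event-assigned TRs.
#' @return data.frame of class `attention_metrics`, one row per state:
#'   `subject_id`, `state`, `percent_time`, `n_events`, `mean_duration_s`,
#'   `sd_duration_s` (NA when fewer than 2 events).
#' @export
compute_attention_metrics <- function(decoded, events = NULL,
                                      subject_id = "subject",
                                      events_only = FALSE) {
  stopifnot(inherits(decoded, "decoded_session"))
  if (is.null(events)) events <- segment_mental_events(decoded)
  check_events_against_decisions(events, decoded$decisions)
  states <- decoded$state_set
  tr_sec <- decoded$tr_seconds
  rows <- lapply(states, function(s) {
    ev <- events[events$state == s, , drop = FALSE]
    trs <- if (events_only) sum(ev$duration_trs) else
      sum(decoded$decisions == s)
    dur_s <- ev$duration_trs * tr_sec
    data.frame(subject_id = subject_id, state = s,
               percent_time = 100 * trs / decoded$n_trs,
               n_events = nrow(ev),
               mean_duration_s = if (nrow(ev) > 0) mean(dur_s) else NA_real_,
               sd_duration_s = if (nrow(ev) >= 2) stats::sd(dur_s)
               else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("attention_metrics", "data.frame")
  out
}

# every event must span TRs that all carry its state in the decisions
check_events_against_decisions <- function(events, decisions) {
  decisions <- as.character(decisions)
  for (i in seq_len(nrow(events))) {
    span <- events$onset_tr[i] + seq_len(events$duration_trs[i])
    if (max(span) > length(decisions) ||
        any(decisions[span] != events$state[i]))
      stop("events do not match the decision sequence they claim to segment",
           call. = FALSE)
  }
  invisible(events)
}

new_group_stats <- function(test, estimate, t, df, p, cohens_d, n) {
  structure(list(test = test, estimate = estimate, t = t, df = df, p = p,
                 cohens_d = cohens_d, n = n), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> %s: estimate = %.4g, t(%d) = %.3f, p = %.3g, d = %.3f, n = %d\n",
              x$test, x$estimate, x$df, x$t, x$p, x$cohens_d, x$n))
  invisible(x)
}

#' One-sample t-test of per-subject statistics against a reference
#'
#' Two-sided one-sample t-test (e.g. mean per-condition accuracy against the
#' 20% five-class chance level), with Cohen's d = (mean - reference) /
#' sample SD.
#'
#' @param values Per-subject statistics (n >= 2, non-constant).
#' @param reference Null value tested against.
#' @return A `group_stats` object.
#' @export
group_accuracy_ttest <- function(values, reference) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2 subjects", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("zero variance across subjects; t-test undefined", call. = FALSE)
  tt <- stats::t.test(values, mu = reference)
  new_group_stats(
    test = sprintf("one-sample t vs %g", reference),
    estimate = mean(values), t = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value,
    cohens_d = (mean(values) - reference) / stats::sd(values),
    n = length(values))
}

#' Group test of within-subject correlations via Fisher r-to-Z
#'
#' Transforms per-subject Pearson correlations with Z = arctanh(r) and tests
#' the mean Z against 0 with a two-sided one-sample t-test. Missing
#' correlations (undefined within a subject) are excluded with a logged
#' count; |r| = 1 is rejected (infinite Z).
#'
#' @param correlations Per-subject r values in (-1, 1), possibly with `NA`.
#' @return A `group_stats` object; `estimate` is the mean Z.
#' @export
fisher_z_group_test <- function(correlations) {
  r <- as.numeric(correlations)
  n_na <- sum(is.na(r))
  if (n_na > 0L) {
    message(sprintf("fisher_z_group_test: excluding %d undefined r value(s)",
                    n_na))
    r <- r[!is.na(r)]
  }
  if (any(abs(r) >= 1))
    stop("|r| = 1 present: Fisher Z is infinite", call. = FALSE)
  if (length(r) < 2L) stop("need n >= 2 defined correlations", call. = FALSE)
  z <- atanh(r)
  if (stats::sd(z) == 0)
    stop("zero variance across subjects; t-test undefined", call. = FALSE)
  tt <- stats::t.test(z, mu = 0)
  new_group_stats(
    test = "Fisher r-to-Z, one-sample t vs 0",
    estimate = mean(z), t = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value,
    cohens_d = mean(z) / stats::sd(z), n = length(z))
}

#' Paired comparison of breath attention against another state
#'
#' Paired two-sided t-test of a per-subject metric (default `percent_time`)
#' for Breath minus the chosen other state (MW or Self), with Cohen's d on
#' the difference scores.
#'
#' @param metrics_list List of per-subject [compute_attention_metrics()]
#'   data.frames (or one stacked data.frame with a `subject_id` column).
#' @param other_state `"MW"` or `"Self"`.
#' @param metric Metric column to compare, default `"percent_time"`.
#' @return A `group_stats` object; `estimate` is the mean paired difference.
#' @export
compare_breath_vs_other <- function(metrics_list, other_state = c("MW", "Self"),
                                    metric = "percent_time") {
  other_state <- match.arg(other_state)
  df <- if (is.data.frame(metrics_list)) metrics_list else
    do.call(rbind, metrics_list)
  stopifnot(metric %in% names(df))
  wide <- stats::reshape(
    df[, c("subject_id", "state", metric)],
    idvar = "subject_id", timevar = "state", direction = "wide")
  bcol <- paste0(metric, ".Breath"); ocol <- paste0(metric, ".", other_state)
  if (!all(c(bcol, ocol) %in% names(wide)) || anyNA(wide[[bcol]]) ||
      anyNA(wide[[ocol]]))
    stop("every subject needs paired Breath and ", other_state, " values",
         call. = FALSE)
  d <- wide[[bcol]] - wide[[ocol]]
  if (length(d) < 2L) stop("need n >= 2 subjects", call. = FALSE)
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences; t-test undefined",
         call. = FALSE)
  tt <- stats::t.test(wide[[bcol]], wide[[ocol]], paired = TRUE)
  new_group_stats(
    test = sprintf("paired t, Breath vs %s (%s)", other_state, metric),
    estimate = mean(d), t = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value,
    cohens_d = mean(d) / stats::sd(d), n = length(d))
}

#' Agreement between decoded decisions and synthetic ground truth
#'
#' Fraction of TRs whose decoded state equals the hidden state that generated
#' the data. Only meaningful for synthetic sessions, where the truth exists.
#'
#' @param decoded A [decode_meditation()] result.
#' @param truth A [meditation_truth()] of equal length.
#' @return Fraction in \[0, 1\].
#' @export
sequence_recovery_score <- function(decoded, truth) {
  stopifnot(inherits(decoded, "decoded_session"),
            inherits(truth, "meditation_truth"))
  if (decoded$n_trs != length(truth$state_sequence))
    stop("decoded session and truth differ in length", call. = FALSE)
  mean(as.character(decoded$decisions) ==
         as.character(truth$state_sequence))
}
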