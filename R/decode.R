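#' Decode a meditation period TR by TR
#'
#' Applies a subject's trained 5-state classifier to each TR of an unlabeled
#' meditation time series, restricts the class probabilities to the
#' meditation-relevant state set (Breath, MW, Self), renormalizes, and
#' decides by argmax. Ties are broken deterministically by the fixed state
#' order (Breath < MW < Self) and logged.
#'
#' @param classifier A [train_state_classifier()] result; its voxel ordering
#'   must match the meditation series.
#' @param meditation_ts A [voxel_timeseries()] of the meditation period.
#' @param state_set Decoded state subset, default [meditation_states()];
#'   must be a subset of the classifier's states.
#' @return Object of class `decoded_session`: `decisions` (factor per TR),
#'   `probabilities` (TRs x states, rows sum to 1), `n_trs`, `state_set`,
#'   `tr_seconds`.
#' @export
decode_meditation <- function(classifier, meditation_ts,
                              state_set = meditation_states()) {
  stopifnot(inherits(classifier, "subject_classifier"))
  validate_voxel_timeseries(meditation_ts)
  if (!all(state_set %in% classifier$states))
    stop("state_set must be a subset of the classifier's states",
         call. = FALSE)
  pr5 <- predict_state_probs(classifier, meditation_ts$data)
  pr <- pr5[, state_set, drop = FALSE]
  pr <- pr / rowSums(pr)
  decisions <- decide_states(pr, states = state_set)
  structure(list(decisions = decisions, probabilities = pr,
                 n_trs = nrow(pr), state_set = state_set,
                 tr_seconds = meditation_ts$tr_seconds),
            class = "decoded_session")
}

#' @export
print.decoded_session <- function(x, ...) {
  cat(sprintf("<decoded_session> %d TRs over {%s}\n", x$n_trs,
              paste(x$state_set, collapse = ", ")))
  print(round(100 * table(x$decisions) / x$n_trs, 1))
  invisible(x)
}

#' Segment decoded decisions into mental events
#'
#' A mental event is a maximal run of at least `min_len` consecutive
#' identical state decisions; shorter runs yield no event and their TRs stay
#' unassigned.
#'
#' @param decisions Factor or character per-TR state sequence (non-empty), or
#'   a [decode_meditation()] result.
#' @param min_len Minimum run length in TRs (default 3).
#' @return data.frame of class `mental_events` with columns `state`,
#'   `onset_tr` (0-based), `duration_trs`.
#' @export
segment_mental_events <- function(decisions, min_len = 3L) {
  if (inherits(decisions, "decoded_session")) decisions <- decisions$decisions
  decisions <- as.character(decisions)
  if (length(decisions) == 0L) stop("empty decision sequence", call. = FALSE)
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  runs <- rle(decisions)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths          # 0-based onsets
  keep <- runs$lengths >= min_len
  out <- data.frame(state = runs$values[keep],
                    onset_tr = starts[keep],
                    duration_trs = runs$lengths[keep])
  class(out) <- c("mental_events", "data.frame")
  out
}
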