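#' Voxel-by-time brain pattern matrix
#'
#' Container for a masked 4D BOLD series: one row per time point (TR), one
#' column per in-mask voxel. This is the unit of classification and decoding;
#' all spatial structure beyond a stable voxel ordering is carried separately
#' by the [brain_mask()] used to extract it.
#'
#' @param data Numeric matrix, rows = TRs, columns = voxels. No missing
#'   values are allowed.
#' @param tr_seconds Duration of one TR in seconds (> 0).
#' @param voxel_ids Character or integer vector naming the voxel columns in a
#'   stable order; defaults to `v1..vP`.
#' @param subject_id Opaque subject label.
#'
#' @return An object of class `voxel_timeseries` with fields `data`,
#'   `tr_seconds`, `voxel_ids`, `subject_id`.
#' @export
voxel_timeseries <- function(data, tr_seconds = 1, voxel_ids = NULL,
                             subject_id = "subject") {
  data <- as.matrix(data)
  if (is.null(voxel_ids)) voxel_ids <- paste0("v", seq_len(ncol(data)))
  out <- structure(
    list(data = data, tr_seconds = tr_seconds,
         voxel_ids = as.character(voxel_ids), subject_id = subject_id),
    class = "voxel_timeseries")
  validate_voxel_timeseries(out)
  out
}

validate_voxel_timeseries <- function(ts) {
  stopifnot(inherits(ts, "voxel_timeseries"))
  if (nrow(ts$data) < 1L || ncol(ts$data) < 1L)
    stop("time series needs at least 1 TR and 1 voxel", call. = FALSE)
  if (!is.numeric(ts$tr_seconds) || length(ts$tr_seconds) != 1L ||
      ts$tr_seconds <= 0)
    stop("tr_seconds must be a single positive number", call. = FALSE)
  if (length(ts$voxel_ids) != ncol(ts$data))
    stop("voxel_ids length must equal the voxel (column) count", call. = FALSE)
  if (anyNA(ts$data) || any(!is.finite(ts$data)))
    stop("time series contains missing or non-finite values", call. = FALSE)
  invisible(ts)
}

#' @export
print.voxel_timeseries <- function(x, ...) {
  cat(sprintf("<voxel_timeseries> subject %s: %d TRs x %d voxels, TR = %gs\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Binary brain mask on a 3D grid
#'
#' @param shape Integer vector of length 3, the 3D grid dimensions.
#' @param included Integer vector of linear (column-major) voxel indices
#'   inside the mask, in the deterministic order used for the columns of the
#'   masked time series.
#'
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(shape, included) {
  shape <- as.integer(shape)
  included <- as.integer(included)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (length(included) == 0L) stop("mask includes no voxels", call. = FALSE)
  if (any(included < 1L) || any(included > prod(shape)))
    stop("mask coordinates fall outside the grid", call. = FALSE)
  structure(list(shape = shape, included = included), class = "brain_mask")
}

#' Internal-attention task design
#'
#' Ordered trial table for one internal-attention (IA) session: for every
#' trial its condition (one of the five states, or `Instruction` for the
#' auditory cue preceding each stimulus trial), onset and duration in seconds,
#' block index, and an optional post-trial attention rating (1-4; never
#' collected for MW trials).
#'
#' @param trials data.frame with columns `condition`, `onset`, `duration`,
#'   `block` and optionally `rating`.
#' @param n_blocks Number of task blocks.
#' @param order_set_id Which of the four fixed condition-order sets was used
#'   (1-4); informational.
#' @param tr_seconds TR duration in seconds.
#' @param per_condition_block_seconds Seconds of stimulus data collected per
#'   condition in each block (72 by default); used for validation.
#'
#' @return An object of class `ia_design`.
#' @export
ia_design <- function(trials, n_blocks = max(trials$block), order_set_id = 1L,
                      tr_seconds = 1, per_condition_block_seconds = 72) {
  trials <- as.data.frame(trials)
  req <- c("condition", "onset", "duration", "block")
  miss <- setdiff(req, names(trials))
  if (length(miss) > 0L)
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"rating" %in% names(trials)) trials$rating <- NA_integer_
  bad <- setdiff(unique(as.character(trials$condition)), trial_conditions())
  if (length(bad) > 0L)
    stop("unknown trial_type value(s): ", paste(dQuote(bad), collapse = ", "),
         call. = FALSE)
  trials$condition <- factor(as.character(trials$condition),
                             levels = trial_conditions())
  out <- structure(
    list(trials = trials, n_blocks = as.integer(n_blocks),
         order_set_id = as.integer(order_set_id), tr_seconds = tr_seconds,
         per_condition_block_seconds = per_condition_block_seconds),
    class = "ia_design")
  # structural checks only; the per-block stimulus-second budget is enforced
  # by validate_ia_design(design) on complete designs
  validate_ia_design(out, check_budget = FALSE)
  out
}

#' Validate an IA design against its structural invariants
#'
#' Checks positive durations, stimulus trial durations within 16-50 s,
#' ratings absent from MW and Instruction trials, non-overlapping time-ordered
#' trials within each block, the presence of every block index, and (when
#' `check_budget`) that stimulus seconds per condition per block sum exactly
#' to `per_condition_block_seconds`.
#'
#' @param design An [ia_design()].
#' @param check_budget Verify the per-block per-condition stimulus-second
#'   budget; disable for hand-built fragments.
#' @param trial_bounds Allowed stimulus trial duration range in seconds.
#' @return The design, invisibly; errors describe the first violation.
#' @export
validate_ia_design <- function(design, check_budget = TRUE,
                               trial_bounds = c(16, 50)) {
  stopifnot(inherits(design, "ia_design"))
  tr <- design$trials
  if (any(tr$duration <= 0))
    stop("all trial durations must be positive", call. = FALSE)
  stim <- tr$condition != "Instruction"
  if (any(tr$duration[stim] < trial_bounds[1] |
          tr$duration[stim] > trial_bounds[2]))
    stop(sprintf("stimulus trial durations must lie in [%g, %g] s",
                 trial_bounds[1], trial_bounds[2]), call. = FALSE)
  if (any(!is.na(tr$rating) & tr$condition %in% c("MW", "Instruction")))
    stop("ratings are never collected for MW or Instruction trials",
         call. = FALSE)
  if (any(!is.na(tr$rating) & !(tr$rating %in% 1:4)))
    stop("ratings must be integers 1-4", call. = FALSE)
  if (!setequal(unique(tr$block), seq_len(design$n_blocks)))
    stop("blocks must be exactly 1..n_blocks", call. = FALSE)
  for (b in seq_len(design$n_blocks)) {
    tb <- tr[tr$block == b, ]
    if (is.unsorted(tb$onset, strictly = FALSE))
      stop("trials within a block must be time-ordered", call. = FALSE)
    if (nrow(tb) > 1L &&
        any(tb$onset[-1L] < (tb$onset + tb$duration)[-nrow(tb)] - 1e-9))
      stop("trials within a block overlap", call. = FALSE)
    if (check_budget) {
      for (cond in attention_states()) {
        tot <- sum(tb$duration[tb$condition == cond])
        if (abs(tot - design$per_condition_block_seconds) > 1e-9)
          stop(sprintf(
            "block %d condition %s has %g stimulus seconds, expected %g",
            b, cond, tot, design$per_condition_block_seconds), call. = FALSE)
      }
    }
  }
  invisible(design)
}

#' @export
print.ia_design <- function(x, ...) {
  cat(sprintf(
    "<ia_design> %d blocks, order set %d, %d trials (%d stimulus), TR = %gs\n",
    x$n_blocks, x$order_set_id, nrow(x$trials),
    sum(x$trials$condition != "Instruction"), x$tr_seconds))
  invisible(x)
}

#' Labeled training samples for state classification
#'
#' TR-level feature matrix with one condition label per sample, carrying the
#' block and trial provenance needed for leave-one-block-out cross-validation
#' and per-trial accuracy summaries.
#'
#' @param features Numeric matrix, samples x voxels.
#' @param labels Condition per sample (one of the five states; never
#'   `Instruction`).
#' @param blocks Integer block index per sample.
#' @param trial_ids Identifier of the originating trial per sample.
#'
#' @return An object of class `labeled_samples`.
#' @export
labeled_samples <- function(features, labels, blocks, trial_ids) {
  features <- as.matrix(features)
  labels <- as_state_factor(labels)
  n <- nrow(features)
  if (length(labels) != n || length(blocks) != n || length(trial_ids) != n)
    stop("features, labels, blocks and trial_ids must share sample count",
         call. = FALSE)
  structure(
    list(features = features, labels = labels, blocks = as.integer(blocks),
         trial_ids = as.character(trial_ids)),
    class = "labeled_samples")
}

#' @export
print.labeled_samples <- function(x, ...) {
  cat(sprintf("<labeled_samples> %d samples x %d voxels over %d blocks\n",
              nrow(x$features), ncol(x$features), length(unique(x$blocks))))
  print(table(x$labels))
  invisible(x)
}
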