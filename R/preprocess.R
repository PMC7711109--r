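#' Detrend and standardize a voxel time series
#'
#' Per-voxel linear detrending (ordinary least squares on time) and/or
#' z-scoring (mean 0, unit sample SD per voxel column). Voxels whose column is
#' constant cannot be standardized; they are set to all-zero and reported via
#' a message, never dropped, so that voxel ordering stays stable for
#' importance maps.
#'
#' @param ts A [voxel_timeseries()].
#' @param detrend Remove a per-voxel least-squares linear trend.
#' @param zscore Standardize each voxel column to mean 0, sample SD 1.
#' @return A new [voxel_timeseries()] with the same shape and voxel order.
#' @export
preprocess_timeseries <- function(ts, detrend = TRUE, zscore = TRUE) {
  validate_voxel_timeseries(ts)
  x <- ts$data
  n <- nrow(x)
  if (detrend && n >= 2L) {
    # residuals of the per-voxel OLS fit on time (removes intercept + slope)
    t_c <- seq_len(n) - mean(seq_len(n))
    slope <- drop(crossprod(t_c, x)) / sum(t_c^2)
    x <- sweep(x, 2, colMeans(x), "-") - outer(t_c, slope)
  }
  if (zscore) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    degenerate <- !is.finite(sdv) | sdv < .Machine$double.eps^0.5
    n_deg <- sum(degenerate)
    if (n_deg > 0L) {
      message(sprintf(
        "preprocess_timeseries: %d constant voxel(s) set to zero (kept in place)",
        n_deg))
      sdv[degenerate] <- 1
    }
    x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
    if (n_deg > 0L) x[, degenerate] <- 0
  }
  voxel_timeseries(x, tr_seconds = ts$tr_seconds, voxel_ids = ts$voxel_ids,
                   subject_id = ts$subject_id)
}

#' Extract labeled TR samples from a session
#'
#' Attributes each TR to the stimulus trial it falls inside, after shifting by
#' a hemodynamic lag: the row at TR index `t` (0-based) is labeled by the
#' trial containing time `(t - lag_trs) * tr_seconds`, under the half-open
#' convention `onset <= time < onset + duration`. Instruction TRs, TRs in no
#' trial, and TRs pushed past either scan edge are excluded. Sample order is
#' time order.
#'
#' @param ts A [voxel_timeseries()].
#' @param design An [ia_design()] whose trial times fall within the scan.
#' @param lag_trs Non-negative integer hemodynamic delay in TRs. The default
#'   0 matches the synthetic generator, which applies no hemodynamic
#'   convolution; use 4-6 TRs for real BOLD data.
#' @return A [labeled_samples()] object.
#' @export
extract_labeled_samples <- function(ts, design, lag_trs = 0L) {
  validate_voxel_timeseries(ts)
  stopifnot(inherits(design, "ia_design"))
  lag_trs <- as.integer(lag_trs)
  if (lag_trs < 0L) stop("lag_trs must be >= 0", call. = FALSE)
  tr_sec <- ts$tr_seconds
  n_trs <- nrow(ts$data)
  trials <- design$trials
  stim <- trials[trials$condition != "Instruction", , drop = FALSE]
  rows <- integer(0); labs <- character(0); blks <- integer(0)
  tids <- character(0)
  stim_ids <- rownames(stim)
  if (is.null(stim_ids)) stim_ids <- as.character(seq_len(nrow(stim)))
  for (i in seq_len(nrow(stim))) {
    # 0-based TR indices whose (unshifted) start time lies inside the trial
    first <- ceiling(stim$onset[i] / tr_sec - 1e-9)
    last <- ceiling((stim$onset[i] + stim$duration[i]) / tr_sec - 1e-9) - 1L
    if (last < first) next
    idx <- seq.int(first, last) + lag_trs          # shifted row indices
    idx <- idx[idx >= 0L & idx < n_trs]
    if (length(idx) == 0L) next
    rows <- c(rows, idx)
    labs <- c(labs, rep(as.character(stim$condition[i]), length(idx)))
    blks <- c(blks, rep(stim$block[i], length(idx)))
    tids <- c(tids, rep(paste0("trial", stim_ids[i]), length(idx)))
  }
  if (length(rows) == 0L)
    stop("no TR falls inside any stimulus trial after the lag shift",
         call. = FALSE)
  ord <- order(rows)
  labeled_samples(ts$data[rows[ord] + 1L, , drop = FALSE], labs[ord],
                  blks[ord], tids[ord])
}
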