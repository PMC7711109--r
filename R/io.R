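#' Load a BOLD session from NIfTI + events files
#'
#' Reads a 4D BOLD NIfTI, restricts it to the voxels of a 3D mask NIfTI on the
#' same grid (in deterministic column-major voxel order), and parses a
#' BIDS-style events TSV into an [ia_design()].
#'
#' @param bold_path Path to a 4D NIfTI (.nii / .nii.gz).
#' @param mask_path Path to a 3D NIfTI whose nonzero voxels define the mask.
#' @param events_path Path to a tab-separated events file with columns
#'   `onset`, `duration`, `trial_type`, and optionally `block` and `rating`;
#'   `NULL` for unannotated scans (e.g. a meditation period), in which case
#'   the returned `design` is `NULL`.
#' @param tr_seconds TR duration; if `NULL`, taken from the BOLD header.
#' @param subject_id Subject label attached to the time series.
#'
#' @return List with elements `ts` ([voxel_timeseries()]), `design`
#'   ([ia_design()]) and `mask` ([brain_mask()]).
#' @export
load_session <- function(bold_path, mask_path, events_path = NULL,
                         tr_seconds = NULL, subject_id = "subject") {
  bold <- RNifti::readNifti(bold_path)
  mask <- RNifti::readNifti(mask_path)
  bdim <- dim(bold)
  mdim <- dim(mask)
  if (length(bdim) != 4L)
    stop("BOLD image must be 4D, got ", length(bdim), "D", call. = FALSE)
  if (length(mdim) != 3L || !all(mdim == bdim[1:3]))
    stop(sprintf(
      "mask grid (%s) does not align with BOLD grid (%s)",
      paste(mdim, collapse = "x"), paste(bdim[1:3], collapse = "x")),
      call. = FALSE)
  if (is.null(tr_seconds)) {
    tr_seconds <- RNifti::pixdim(bold)[4]
    if (!is.finite(tr_seconds) || tr_seconds <= 0) tr_seconds <- 1
  }
  included <- which(as.array(mask) != 0)
  msk <- brain_mask(mdim, included)
  vox_by_time <- matrix(as.numeric(bold), nrow = prod(bdim[1:3]),
                        ncol = bdim[4])
  data <- t(vox_by_time[included, , drop = FALSE])
  ts <- voxel_timeseries(data, tr_seconds = tr_seconds,
                         voxel_ids = paste0("v", included),
                         subject_id = subject_id)
  design <- NULL
  if (!is.null(events_path)) {
    design <- read_events(events_path, tr_seconds = tr_seconds)
    scan_end <- nrow(data) * tr_seconds
    tr_end <- design$trials$onset + design$trials$duration
    if (any(tr_end > scan_end + 1e-9))
      stop(sprintf("events extend past the scan end (%g s > %g s)",
                   max(tr_end), scan_end), call. = FALSE)
  }
  list(ts = ts, design = design, mask = msk)
}

#' Read a BIDS-style events TSV into an IA design
#'
#' @inheritParams load_session
#' @param per_condition_block_seconds When a number, the full per-block
#'   per-condition stimulus-second budget is verified against it; `NA` (the
#'   default) validates structure only, so partial sessions load cleanly.
#' @return An [ia_design()].
#' @export
read_events <- function(events_path, tr_seconds = 1,
                        per_condition_block_seconds = NA) {
  ev <- utils::read.delim(events_path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("onset", "duration", "trial_type")
  miss <- setdiff(req, names(ev))
  if (length(miss) > 0L)
    stop("events file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  trials <- data.frame(
    condition = ev$trial_type,
    onset = as.numeric(ev$onset),
    duration = as.numeric(ev$duration),
    block = if ("block" %in% names(ev)) as.integer(ev$block) else 1L,
    rating = if ("rating" %in% names(ev)) {
      suppressWarnings(as.integer(ev$rating))
    } else NA_integer_)
  check <- !is.na(per_condition_block_seconds)
  d <- ia_design(trials, tr_seconds = tr_seconds,
                 per_condition_block_seconds =
                   if (check) per_condition_block_seconds else 72)
  if (!check) return(d)
  validate_ia_design(d)
  d
}

# near-cubic 3D grid large enough to hold n voxels
grid_for_voxels <- function(n_voxels) {
  side <- ceiling(n_voxels^(1 / 3))
  shape <- c(side, side, ceiling(n_voxels / side^2))
  stopifnot(prod(shape) >= n_voxels)
  as.integer(shape)
}

#' Write a session to NIfTI + events TSV
#'
#' Serializes a masked time series back onto a 3D grid (synthetic sessions use
#' a compact near-cubic grid with the voxels occupying the first mask
#' positions), writes the 4D BOLD and 3D mask as NIfTI, the design as a
#' BIDS-style events TSV, optionally a per-TR hidden-state truth TSV, and a
#' JSON manifest of what was written.
#'
#' @param ts A [voxel_timeseries()].
#' @param design An [ia_design()] or `NULL`.
#' @param dir Output directory (created if needed).
#' @param mask A [brain_mask()]; defaults to a compact synthetic grid.
#' @param truth Optional [meditation_truth] whose per-TR state sequence is
#'   written as `truth.tsv`.
#' @param prefix File name prefix, default `"session"`.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_session <- function(ts, design = NULL, dir, mask = NULL, truth = NULL,
                          prefix = "session") {
  validate_voxel_timeseries(ts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- ncol(ts$data)
  if (is.null(mask)) mask <- brain_mask(grid_for_voxels(p), seq_len(p))
  if (length(mask$included) != p)
    stop("mask voxel count does not match the time series", call. = FALSE)
  n_trs <- nrow(ts$data)
  vol <- array(0, dim = c(mask$shape, n_trs))
  flat <- matrix(0, nrow = prod(mask$shape), ncol = n_trs)
  flat[mask$included, ] <- t(ts$data)
  vol[] <- flat
  bold_path <- file.path(dir, paste0(prefix, "_bold.nii.gz"))
  mask_path <- file.path(dir, paste0(prefix, "_mask.nii.gz"))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(1, 1, 1, ts$tr_seconds)
  RNifti::writeNifti(img, bold_path)
  mvol <- array(0L, dim = mask$shape)
  mvol[mask$included] <- 1L
  RNifti::writeNifti(RNifti::asNifti(mvol), mask_path)
  paths <- list(bold = bold_path, mask = mask_path)
  if (!is.null(design)) {
    events_path <- file.path(dir, paste0(prefix, "_events.tsv"))
    write_events(design, events_path)
    paths$events <- events_path
  }
  if (!is.null(truth)) {
    truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
    utils::write.table(
      data.frame(tr = seq_along(truth$state_sequence) - 1L,
                 state = as.character(truth$state_sequence)),
      truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$truth <- truth_path
  }
  manifest_path <- file.path(dir, paste0(prefix, "_manifest.json"))
  write_manifest(manifest_path, list(
    subject_id = ts$subject_id, n_trs = n_trs, n_voxels = p,
    tr_seconds = ts$tr_seconds, grid = mask$shape,
    files = lapply(paths, basename)))
  paths$manifest <- manifest_path
  invisible(paths)
}

#' Write an IA design as a BIDS-style events TSV
#'
#' @param design An [ia_design()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events <- function(design, path) {
  tr <- design$trials
  out <- data.frame(onset = tr$onset, duration = tr$duration,
                    trial_type = as.character(tr$condition),
                    block = tr$block,
                    rating = ifelse(is.na(tr$rating), "n/a", tr$rating))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# manifest helper shared by writers and the pipeline
write_manifest <- function(path, fields) {
  fields$written_by <- paste0("mindstates ",
                              as.character(utils::packageVersion("mindstates")))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
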