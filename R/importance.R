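#' Classifier importance map for one condition
#'
#' Per voxel, importance = (classifier weight for predicting the condition)
#' x (z-scored mean activation of the voxel during the condition). The
#' condition-mean activation vector is z-scored across voxels; the sign of
#' that z-scored activation is recorded per voxel so thresholded maps can be
#' split into positively and negatively activated importance voxels. (An
#' alternative reading — z-scoring each voxel over time before averaging —
#' is available via `zscore_over = "time"`.)
#'
#' @param classifier A [train_state_classifier()] result.
#' @param samples The [labeled_samples()] the classifier was trained on (or a
#'   compatible sample set on the same voxel grid).
#' @param condition One of the five states, present in `samples`.
#' @param zscore_over `"voxels"` (default) z-scores the condition-mean
#'   activation across voxels; `"time"` z-scores each voxel's time course
#'   first and averages the z-scores within the condition.
#' @return Object of class `importance_map`: `values`, `activation_sign`,
#'   `condition`, `threshold_sd` (`NA` until thresholded), `flagged`.
#' @export
compute_importance_map <- function(classifier, samples, condition,
                                   zscore_over = c("voxels", "time")) {
  stopifnot(inherits(classifier, "subject_classifier"),
            inherits(samples, "labeled_samples"))
  zscore_over <- match.arg(zscore_over)
  if (!condition %in% levels(samples$labels) ||
      !any(samples$labels == condition))
    stop(sprintf("condition %s absent from samples", dQuote(condition)),
         call. = FALSE)
  if (ncol(samples$features) != ncol(classifier$weights))
    stop("samples and classifier disagree on voxel count", call. = FALSE)
  rows <- samples$labels == condition
  if (zscore_over == "voxels") {
    m <- colMeans(samples$features[rows, , drop = FALSE])
    sdv <- stats::sd(m)
    z <- if (sdv > 0) (m - mean(m)) / sdv else rep(0, length(m))
  } else {
    zs <- scale(samples$features)
    zs[, attr(zs, "scaled:scale") == 0] <- 0
    z <- colMeans(zs[rows, , drop = FALSE])
  }
  w <- classifier$weights[condition, ]
  structure(list(values = as.numeric(w * z),
                 activation_sign = sign(z),
                 condition = condition,
                 threshold_sd = NA_real_,
                 flagged = NULL),
            class = "importance_map")
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf("<importance_map> %s: %d voxels%s\n", x$condition,
              length(x$values),
              if (is.null(x$flagged)) " (unthresholded)"
              else sprintf(", %d flagged at +/- %g SD", nrow(x$flagged),
                           x$threshold_sd)))
  invisible(x)
}

#' Threshold an importance map at +/- k SD
#'
#' Flags voxels whose importance deviates from the map mean by more than
#' `k_sd` population standard deviations of the within-map importance
#' distribution; flagged voxels carry the positive/negative class of their
#' z-scored mean activation. `center = "zero"` applies the cutoff around 0
#' instead of the map mean. A zero-variance map flags nothing, with a note.
#'
#' @param map A [compute_importance_map()] result with >= 2 voxels.
#' @param k_sd SD multiplier, default 2.
#' @param center `"mean"` (default) or `"zero"`.
#' @return The map with `flagged` set: data.frame of `voxel` (index),
#'   `importance`, `sign` (+1/-1/0 from activation sign).
#' @export
threshold_importance <- function(map, k_sd = 2, center = c("mean", "zero")) {
  stopifnot(inherits(map, "importance_map"))
  center <- match.arg(center)
  v <- map$values
  if (length(v) < 2L) stop("need >= 2 voxels to threshold", call. = FALSE)
  mu <- if (center == "mean") mean(v) else 0
  sdv <- sqrt(mean((v - mean(v))^2))      # population SD of the map
  if (sdv == 0) {
    message("threshold_importance: zero-variance map, nothing flagged")
    idx <- integer(0)
  } else {
    idx <- which(abs(v - mu) > k_sd * sdv)
  }
  map$threshold_sd <- k_sd
  map$flagged <- data.frame(voxel = idx, importance = v[idx],
                            sign = map$activation_sign[idx])
  map
}

#' Group importance frequency map
#'
#' Counts, per voxel, how many subjects' thresholded importance maps flag it
#' — overall and split by positive/negative activation class — together with
#' a histogram of the overall counts over ever-flagged voxels.
#'
#' @param maps List of thresholded [importance_map] objects, one per subject,
#'   on a shared voxel grid (same length and ordering).
#' @return Object of class `frequency_map`: `counts_all`, `counts_positive`,
#'   `counts_negative`, `n_subjects`, `histogram` (data.frame of count value
#'   vs number of voxels, over voxels flagged at least once).
#' @export
importance_frequency_map <- function(maps) {
  if (length(maps) == 0L) stop("no maps supplied", call. = FALSE)
  lens <- vapply(maps, function(m) length(m$values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("maps disagree on voxel count; a shared grid is required",
         call. = FALSE)
  if (any(vapply(maps, function(m) is.null(m$flagged), logical(1))))
    stop("all maps must be thresholded first (see threshold_importance)",
         call. = FALSE)
  p <- lens[1]
  counts_all <- counts_pos <- counts_neg <- integer(p)
  for (m in maps) {
    counts_all[m$flagged$voxel] <- counts_all[m$flagged$voxel] + 1L
    pos <- m$flagged$voxel[m$flagged$sign > 0]
    neg <- m$flagged$voxel[m$flagged$sign < 0]
    counts_pos[pos] <- counts_pos[pos] + 1L
    counts_neg[neg] <- counts_neg[neg] + 1L
  }
  ever <- counts_all > 0L
  hist_tab <- table(factor(counts_all[ever], levels = seq_len(length(maps))))
  structure(list(counts_all = counts_all, counts_positive = counts_pos,
                 counts_negative = counts_neg, n_subjects = length(maps),
                 histogram = data.frame(
                   n_subjects_sharing = as.integer(names(hist_tab)),
                   n_voxels = as.integer(hist_tab))),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf(
    "<frequency_map> %d subjects, %d voxels, max sharing %d subject(s)\n",
    x$n_subjects, length(x$counts_all), max(x$counts_all)))
  invisible(x)
}
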