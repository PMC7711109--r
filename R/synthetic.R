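#' Synthetic state-specific voxel patterns
#'
#' Draws one mean activation pattern per attention state. Each pattern is a
#' mixture `sqrt(overlap) * shared + sqrt(1 - overlap) * unique` of a shared
#' Gaussian component and a state-specific Gaussian component, sparsified by
#' keeping the `sparsity` fraction of voxels with largest magnitude and
#' scaled to `amplitude`. `overlap = 0` gives (in expectation) uncorrelated
#' patterns; `overlap = 1` makes all five patterns identical; expected
#' pairwise correlation increases monotonically in between.
#'
#' @param n_voxels Number of voxels (>= 5).
#' @param overlap Pairwise-similarity control in \[0, 1\].
#' @param amplitude Scale of nonzero pattern entries (signal units).
#' @param sparsity Fraction of voxels with nonzero loading per state.
#' @param seed Integer seed; identical arguments reproduce the matrix.
#'
#' @return Object of class `state_patterns`: `patterns` (5 x voxels matrix,
#'   rows in [attention_states()] order), `state_order`, `overlap`, `seed`.
#' @export
make_state_patterns <- function(n_voxels, overlap = 0, amplitude = 1,
                                sparsity = 0.1, seed = 1L) {
  states <- attention_states()
  if (n_voxels < length(states))
    stop("n_voxels must be at least the number of states (5)", call. = FALSE)
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]",
                                       call. = FALSE)
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must lie in (0, 1]",
                                          call. = FALSE)
  k <- max(1L, round(sparsity * n_voxels))
  pat <- with_seed(seed, {
    shared <- stats::rnorm(n_voxels)
    m <- matrix(0, length(states), n_voxels,
                dimnames = list(states, NULL))
    for (s in seq_along(states)) {
      uniq <- stats::rnorm(n_voxels)
      raw <- sqrt(overlap) * shared + sqrt(1 - overlap) * uniq
      keep <- order(abs(raw), decreasing = TRUE)[seq_len(k)]
      row <- numeric(n_voxels)
      row[keep] <- raw[keep] * amplitude
      m[s, ] <- row
    }
    m
  })
  structure(list(patterns = pat, state_order = states, overlap = overlap,
                 seed = as.integer(seed)),
            class = "state_patterns")
}

#' @export
print.state_patterns <- function(x, ...) {
  cat(sprintf("<state_patterns> 5 states x %d voxels, overlap = %g\n",
              ncol(x$patterns), x$overlap))
  invisible(x)
}

# fixed condition orders: cyclic rotations of the canonical state order,
# a Latin-square-style stand-in for the four randomized stimulus order sets
condition_order_sets <- function() {
  states <- attention_states()
  lapply(0:3, function(r) states[(seq_along(states) + r - 1L) %%
                                   length(states) + 1L])
}

# all integer partitions (non-increasing parts) of `total` into `k` parts
# within [lo, hi]
integer_partitions <- function(total, k, lo, hi) {
  if (k == 1L) {
    if (total >= lo && total <= hi) return(list(total))
    return(list())
  }
  upper <- min(hi, total - (k - 1L) * lo)
  if (upper < lo) return(list())
  out <- list()
  for (first in upper:lo) {
    rest <- integer_partitions(total - first, k - 1L, lo, min(hi, first))
    out <- c(out, lapply(rest, function(r) c(first, r)))
  }
  out
}

feasible_partitions <- function(total, trial_bounds, max_trials = 3L) {
  lo <- trial_bounds[1]; hi <- trial_bounds[2]
  k_min <- max(1L, as.integer(ceiling(total / hi)))
  k_max <- min(as.integer(max_trials), as.integer(floor(total / lo)))
  if (k_min > k_max) return(list())
  unlist(lapply(k_min:k_max, function(k) integer_partitions(total, k, lo, hi)),
         recursive = FALSE)
}

#' Build a randomized internal-attention block design
#'
#' Constructs the trial table for an IA session: `n_blocks` blocks, each
#' containing every condition for exactly `per_condition_block_seconds` of
#' stimulus time, split into 2-3 trials whose integer durations are drawn
#' uniformly from the feasible set of partitions with parts in
#' `trial_bounds`. Each stimulus trial is preceded by a short auditory
#' Instruction trial. Within a block, trials cycle through the conditions in
#' the chosen order set (rotated per block by the seed) so conditions
#' interleave. Ratings (1-4) are attached to the last half of non-MW trials,
#' mirroring the acquisition protocol; they carry no signal unless coupled at
#' simulation time.
#'
#' @param n_blocks Number of blocks (default 6).
#' @param per_condition_block_seconds Stimulus seconds per condition per
#'   block (default 72).
#' @param trial_bounds Allowed stimulus trial durations in seconds, default
#'   c(16, 50).
#' @param order_set_id Which of the four fixed condition orders seeds the
#'   block orders (1-4).
#' @param instruction_seconds Length of the auditory instruction before each
#'   trial (default 2).
#' @param tr_seconds TR duration (default 1).
#' @param seed Integer seed.
#' @param max_trials_per_condition Upper bound on trials per condition per
#'   block (default 3).
#' @return An [ia_design()].
#' @export
build_ia_design <- function(n_blocks = 6L, per_condition_block_seconds = 72,
                            trial_bounds = c(16, 50), order_set_id = 1L,
                            instruction_seconds = 2, tr_seconds = 1,
                            seed = 1L, max_trials_per_condition = 3L) {
  if (!order_set_id %in% 1:4)
    stop("order_set_id must be 1..4", call. = FALSE)
  parts_pool <- feasible_partitions(per_condition_block_seconds, trial_bounds,
                                    max_trials_per_condition)
  if (length(parts_pool) == 0L)
    stop(sprintf(
      paste0("no partition of %g s into <= %d trials of [%g, %g] s exists; ",
             "adjust trial_bounds or per_condition_block_seconds"),
      per_condition_block_seconds, max_trials_per_condition,
      trial_bounds[1], trial_bounds[2]), call. = FALSE)
  states <- attention_states()
  base_order <- condition_order_sets()[[order_set_id]]
  with_seed(seed, {
    rows <- list()
    t_cursor <- 0
    for (b in seq_len(n_blocks)) {
      rot <- sample.int(length(states), 1L) - 1L
      block_order <- base_order[(seq_along(states) + rot - 1L) %%
                                  length(states) + 1L]
      durs <- lapply(states, function(s) {
        part <- parts_pool[[sample.int(length(parts_pool), 1L)]]
        if (length(part) > 1L) part <- sample(part)  # shuffle part order
        part
      })
      names(durs) <- states
      nxt <- stats::setNames(rep(1L, length(states)), states)
      repeat {
        placed <- FALSE
        for (cond in block_order) {
          i <- nxt[[cond]]
          if (i > length(durs[[cond]])) next
          rows[[length(rows) + 1L]] <- data.frame(
            condition = "Instruction", onset = t_cursor,
            duration = instruction_seconds, block = b, rating = NA_integer_)
          t_cursor <- t_cursor + instruction_seconds
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cond, onset = t_cursor,
            duration = durs[[cond]][i], block = b, rating = NA_integer_)
          t_cursor <- t_cursor + durs[[cond]][i]
          nxt[[cond]] <- i + 1L
          placed <- TRUE
        }
        if (!placed) break
      }
    }
    trials <- do.call(rbind, rows)
    # ratings on the last half of non-MW stimulus trials
    stim_idx <- which(trials$condition != "Instruction" &
                        trials$condition != "MW")
    rated <- stim_idx[stim_idx > stats::median(which(
      trials$condition != "Instruction"))]
    trials$rating[rated] <- sample(1:4, length(rated), replace = TRUE)
    ia_design(trials, n_blocks = n_blocks, order_set_id = order_set_id,
              tr_seconds = tr_seconds,
              per_condition_block_seconds = per_condition_block_seconds)
  })
}

#' Simulate an internal-attention session
#'
#' Generates BOLD-like data for a block design: every stimulus TR's row is
#' that condition's pattern plus i.i.d. Gaussian noise; Instruction and
#' unassigned TRs carry noise only; an optional per-voxel linear drift is
#' added. No hemodynamic convolution is applied, so TR labels are exact
#' ground truth at lag 0. With the same seed, the underlying standard-normal
#' noise draws are identical across `noise_sd` values (noise is scaled after
#' drawing), giving matched-noise ladders for monotonicity checks.
#'
#' @param patterns A [make_state_patterns()] result.
#' @param design An [ia_design()].
#' @param noise_sd Gaussian noise SD (>= 0), signal units.
#' @param drift_amplitude Max absolute per-voxel linear drift over the scan
#'   (0 disables).
#' @param seed Integer seed.
#' @param rating_coupling If > 0, rated trials get their rating re-drawn with
#'   probability proportional to the trial's realized signal-to-noise, making
#'   ratings informative about trial quality; 0 leaves the design's ratings.
#' @return List with `ts` ([voxel_timeseries()]) and `design`.
#' @export
simulate_ia_session <- function(patterns, design, noise_sd = 1,
                                drift_amplitude = 0, seed = 1L,
                                rating_coupling = 0) {
  stopifnot(inherits(patterns, "state_patterns"), inherits(design, "ia_design"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  p <- ncol(patterns$patterns)
  tr_sec <- design$tr_seconds
  scan_end <- max(design$trials$onset + design$trials$duration)
  n_trs <- as.integer(ceiling(scan_end / tr_sec - 1e-9))
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_trs * p), n_trs, p) * noise_sd
    cond_per_tr <- tr_condition_labels(design, n_trs)
    for (s in attention_states()) {
      idx <- which(cond_per_tr == s)
      if (length(idx) > 0L)
        x[idx, ] <- x[idx, , drop = FALSE] +
          matrix(patterns$patterns[s, ], length(idx), p, byrow = TRUE)
    }
    if (drift_amplitude > 0) {
      slopes <- stats::runif(p, -1, 1) * drift_amplitude
      ramp <- seq(0, 1, length.out = n_trs)
      x <- x + outer(ramp, slopes)
    }
    design2 <- design
    if (rating_coupling > 0) {
      design2$trials <- couple_ratings(design, x, cond_per_tr,
                                       patterns, rating_coupling)
    }
    list(ts = voxel_timeseries(x, tr_seconds = tr_sec,
                               subject_id = "synthetic"),
         design = design2)
  })
}

# condition label of every TR (0-based index i covers time [i, i+1) * tr)
tr_condition_labels <- function(design, n_trs) {
  tr_sec <- design$tr_seconds
  lab <- rep(NA_character_, n_trs)
  tr <- design$trials
  for (i in seq_len(nrow(tr))) {
    first <- ceiling(tr$onset[i] / tr_sec - 1e-9)
    last <- ceiling((tr$onset[i] + tr$duration[i]) / tr_sec - 1e-9) - 1L
    if (last >= first)
      lab[seq.int(first, min(last, n_trs - 1L)) + 1L] <-
        as.character(tr$condition[i])
  }
  lab
}

# redraw ratings so higher realized trial signal quality tends to earn a
# higher rating (linear coupling); used to test rating-accuracy association
# under a positive alternative
couple_ratings <- function(design, x, cond_per_tr, patterns, coupling) {
  trials <- design$trials
  rated <- which(!is.na(trials$rating))
  if (length(rated) == 0L) return(trials)
  tr_sec <- design$tr_seconds
  qual <- vapply(rated, function(i) {
    first <- ceiling(trials$onset[i] / tr_sec - 1e-9) + 1L
    last <- ceiling((trials$onset[i] + trials$duration[i]) / tr_sec - 1e-9)
    rows <- x[first:last, , drop = FALSE]
    pat <- patterns$patterns[as.character(trials$condition[i]), ]
    mean(rows %*% pat) / sqrt(sum(pat^2))  # mean projection on own pattern
  }, numeric(1))
  z <- (qual - mean(qual)) / max(stats::sd(qual), .Machine$double.eps)
  score <- coupling * z + (1 - coupling) * stats::rnorm(length(qual))
  trials$rating[rated] <- as.integer(cut(rank(score, ties.method = "first"),
                                         breaks = 4, labels = FALSE))
  trials
}

#' Meditation-period hidden-state ground truth
#'
#' @param state_sequence Factor/character per-TR hidden state over
#'   [meditation_states()].
#' @param transition_matrix 3x3 row-stochastic matrix used to generate it.
#' @return Object of class `meditation_truth` with fields `state_sequence`,
#'   `transition_matrix`, `mean_dwell_trs` (per-state expected run length,
#'   `1 / (1 - diagonal)`).
#' @export
meditation_truth <- function(state_sequence, transition_matrix) {
  check_transition_matrix(transition_matrix)
  seqf <- as_state_factor(state_sequence, levels = meditation_states())
  structure(list(
    state_sequence = seqf,
    transition_matrix = transition_matrix,
    mean_dwell_trs = 1 / pmax(1 - diag(transition_matrix), 1e-12)),
    class = "meditation_truth")
}

check_transition_matrix <- function(P) {
  states <- meditation_states()
  if (!is.matrix(P) || any(dim(P) != length(states)))
    stop("transition matrix must be 3x3 over (Breath, MW, Self)",
         call. = FALSE)
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix rows must be non-negative and sum to 1",
         call. = FALSE)
  invisible(P)
}

#' Transition matrix with a prescribed stationary distribution
#'
#' Builds `P = (1 - a) I + a * 1 pi'` with `a = 1 / mean_dwell`: with
#' probability `1 - a` the chain stays put, otherwise it resamples a state
#' from `pi`. The stationary distribution is exactly `pi` for any
#' `mean_dwell`; the realized expected dwell of state i is
#' `mean_dwell / (1 - pi_i)`.
#'
#' @param stationary Length-3 probability vector over (Breath, MW, Self).
#' @param mean_dwell Resampling time scale in TRs (> 1).
#' @return 3x3 row-stochastic matrix with dimnames over the meditation
#'   states.
#' @export
stationary_transition_matrix <- function(stationary, mean_dwell = 10) {
  stopifnot(length(stationary) == 3L, all(stationary >= 0),
            abs(sum(stationary) - 1) < 1e-9, mean_dwell > 1)
  a <- 1 / mean_dwell
  P <- (1 - a) * diag(3) + a * matrix(stationary, 3, 3, byrow = TRUE)
  dimnames(P) <- list(meditation_states(), meditation_states())
  P
}

# stationary distribution of a row-stochastic matrix via eigen-decomposition
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Simulate a breath-meditation period with hidden Markov states
#'
#' The hidden state evolves as a first-order Markov chain over (Breath, MW,
#' Self) started from the chain's stationary distribution; each TR's row is
#' the current state's pattern plus i.i.d. Gaussian noise.
#'
#' @param patterns A [make_state_patterns()] result (the Breath, MW and Self
#'   rows are used).
#' @param transition_matrix 3x3 row-stochastic matrix over (Breath, MW,
#'   Self); see [stationary_transition_matrix()].
#' @param duration_trs Meditation length in TRs (default 600, i.e. 10 min at
#'   TR = 1 s).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Integer seed.
#' @param tr_seconds TR duration (default 1).
#' @return List with `ts` ([voxel_timeseries()]) and `truth`
#'   ([meditation_truth()]).
#' @export
simulate_meditation_session <- function(patterns, transition_matrix,
                                        duration_trs = 600L, noise_sd = 1,
                                        seed = 1L, tr_seconds = 1) {
  stopifnot(inherits(patterns, "state_patterns"))
  check_transition_matrix(transition_matrix)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  states <- meditation_states()
  p <- ncol(patterns$patterns)
  with_seed(seed, {
    pi0 <- stationary_distribution(transition_matrix)
    s <- integer(duration_trs)
    s[1] <- sample.int(3L, 1L, prob = pi0)
    if (duration_trs > 1L)
      for (t in 2:duration_trs)
        s[t] <- sample.int(3L, 1L, prob = transition_matrix[s[t - 1L], ])
    x <- matrix(stats::rnorm(duration_trs * p), duration_trs, p) * noise_sd
    x <- x + patterns$patterns[states[s], , drop = FALSE]
    list(ts = voxel_timeseries(x, tr_seconds = tr_seconds,
                               subject_id = "synthetic"),
         truth = meditation_truth(states[s], transition_matrix))
  })
}
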