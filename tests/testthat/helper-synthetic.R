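# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small (tens to hundreds of voxels) so the suite stays fast.

# Labeled samples drawn directly from state patterns + Gaussian noise, with
# blocks assigned round-robin within each state. Bypasses the block design
# when only the classifier is under test.
synthetic_samples <- function(n_per_state = 30, n_voxels = 40,
                              noise_sd = 0.5, n_blocks = 3, overlap = 0,
                              amplitude = 1, seed = 1) {
  pat <- make_state_patterns(n_voxels, overlap = overlap,
                             amplitude = amplitude, seed = seed)
  states <- attention_states()
  labels <- rep(states, each = n_per_state)
  x <- withr::with_seed(seed + 1000L, {
    pat$patterns[labels, , drop = FALSE] +
      matrix(stats::rnorm(length(labels) * n_voxels), length(labels),
             n_voxels) * noise_sd
  })
  blocks <- rep(rep(seq_len(n_blocks), length.out = n_per_state), times = 5)
  ids <- paste0(labels, "_t", rep(seq_len(n_per_state), times = 5))
  list(samples = labeled_samples(x, labels, blocks, ids), patterns = pat)
}

# A small but complete block-designed session: 2 blocks x 32 s/condition in
# 16 s trials keeps the scan around 400 TRs.
small_session <- function(n_voxels = 60, noise_sd = 0, n_blocks = 2,
                          seed = 1, overlap = 0, amplitude = 1) {
  pat <- make_state_patterns(n_voxels, overlap = overlap,
                             amplitude = amplitude, seed = seed)
  design <- build_ia_design(n_blocks = n_blocks,
                            per_condition_block_seconds = 32,
                            trial_bounds = c(16, 16), seed = seed)
  sess <- simulate_ia_session(pat, design, noise_sd = noise_sd,
                              seed = seed + 1L)
  samples <- extract_labeled_samples(sess$ts, sess$design)
  list(patterns = pat, design = sess$design, ts = sess$ts, samples = samples)
}

# Hand-built decoded session (for metric arithmetic tests).
fake_decoded <- function(decisions, tr_seconds = 1,
                         state_set = meditation_states()) {
  decisions <- factor(as.character(decisions), levels = state_set)
  n <- length(decisions)
  probs <- matrix(1e-3, n, length(state_set),
                  dimnames = list(NULL, state_set))
  probs[cbind(seq_len(n), as.integer(decisions))] <- 1
  probs <- probs / rowSums(probs)
  structure(list(decisions = decisions, probabilities = probs, n_trs = n,
                 state_set = state_set, tr_seconds = tr_seconds),
            class = "decoded_session")
}

# Minimal accuracy report for eligibility-rule tests.
fake_report <- function(acc, p, chance = 0.2) {
  states <- attention_states()
  structure(list(per_condition_accuracy = stats::setNames(acc, states),
                 per_condition_chisq_p = stats::setNames(p, states),
                 chance_level = chance),
            class = "accuracy_report")
}

# Independent run-length-encoding oracle: a plain loop, no rle().
rle_events_oracle <- function(decisions, min_len = 3L) {
  decisions <- as.character(decisions)
  out <- data.frame(state = character(0), onset_tr = integer(0),
                    duration_trs = integer(0))
  i <- 1L
  n <- length(decisions)
  while (i <= n) {
    j <- i
    while (j < n && decisions[j + 1L] == decisions[i]) j <- j + 1L
    if (j - i + 1L >= min_len)
      out <- rbind(out, data.frame(state = decisions[i], onset_tr = i - 1L,
                                   duration_trs = j - i + 1L))
    i <- j + 1L
  }
  out
}
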