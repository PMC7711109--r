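#' Internal attention states
#'
#' The five internal attention conditions of the training task, in the fixed
#' canonical order used throughout the package for label factors, classifier
#' weight rows, and argmax tie-breaking: attention to the breath, attention to
#' the feet, mind wandering (MW), self-referential processing, and attention
#' to ambient scanner sounds.
#'
#' @return Character vector of the five state names.
#' @export
attention_states <- function() {
  c("Breath", "Feet", "MW", "Self", "Sounds")
}

#' Meditation-relevant attention states
#'
#' The three states a breath-focused meditation period fluctuates between and
#' the decoded state set of [decode_meditation()]: Breath, MW, Self.
#'
#' @return Character vector of the three state names.
#' @export
meditation_states <- function() {
  c("Breath", "MW", "Self")
}

# condition vocabulary accepted in events files: the 5 states plus the
# 2-second auditory instruction periods that precede every stimulus trial
trial_conditions <- function() {
  c(attention_states(), "Instruction")
}

as_state_factor <- function(x, levels = attention_states()) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad) > 0L) {
    stop("unknown state label(s): ", paste(dQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  factor(as.character(x), levels = levels)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, leaving the
# caller's RNG untouched. All stochastic generators funnel through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a stage-specific child seed from a root seed; keeps results
# reproducible from one root seed while decoupling stages. Stays < 2^31.
derive_seed <- function(root_seed, stage_index) {
  stopifnot(is.finite(root_seed), is.finite(stage_index))
  as.integer((as.double(root_seed) * 48271 + as.double(stage_index) * 9973) %%
               2147483647)
}
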