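---
title: "Decoding internal attention: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding internal attention: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindstates)
```

This vignette is the package's account of its science: what is modeled,
which knobs matter, what the synthetic generator does and does not emulate,
and where the design was genuinely open and a choice had to be made.

## The measurement model

A masked fMRI session is a TR × voxel matrix (`voxel_timeseries`): one brain
pattern per second (TR = 1 s by default), one column per in-mask voxel in a
fixed, deterministic order. Attention states are modeled as *distributed,
subject-specific* mean patterns over those voxels — nothing is assumed about
where the informative voxels sit, whether they agree across subjects, or
whether the subject's anatomy resembles a template. That assumption set is
the point: all learning happens within one subject, in native space.

Five internal attention states are distinguished — Breath, Feet, MW (mind
wandering), Self (self-referential processing), Sounds — the first, third
and fourth being the states a breath meditation fluctuates between, and
Feet/Sounds acting as body-internal and external control targets.

### The classifier

`train_state_classifier()` fits multinomial logistic regression with an L2
penalty, minimizing

$$-\sum_i \log p(y_i \mid x_i, W, b) \;+\; \frac{\lambda}{2}\lVert W\rVert_2^2,
\qquad p(y \mid x) = \mathrm{softmax}(Wx + b).$$

*Penalty convention.* "λ = 0.01" is stated as a penalty strength without an
objective; conventions differ across implementations (some scale the
likelihood by 1/n, some scale the penalty). We fix the convention above —
λ multiplies the squared Frobenius norm of the weight matrix against the
*summed* log-likelihood, intercepts unpenalized — and translate it to the
backing ridge solver (`glmnet`, `alpha = 0`) as `lambda = penalty / n`.
With n = 2160 training patterns this is a very light regularization; its
role is numerical (a strictly convex objective with a unique optimum)
rather than statistical. The solver is run at a fixed tolerance (`thresh =
1e-10`) down a short descending lambda path for warm starts, so refitting
identical data reproduces the model and sample order does not matter beyond
floating-point noise (asserted at 1e-8 in the tests).

### Cross-validation and eligibility

Folds are task *blocks* (leave-one-block-out, k = 6 under the default
design). Blocks are the natural exchangeable unit: TRs within a block share
slow scanner drifts and carry-over effects, so k-fold splits at the TR
level would leak temporal structure into the held-out set. Every TR is
predicted exactly once while held out; decisions aggregate into a 5 × 5
confusion matrix with 432 TRs per true condition.

Each condition's accuracy is tested against the 5-class chance level (20%)
with a 1-df goodness-of-fit chi-square on (correct, incorrect) counts,
without continuity correction — at n = 432 the correction changes nothing
at the reported precision. A subject is *eligible* for meditation decoding
when at least 2 of the 3 meditation-relevant conditions (Breath, MW, Self)
are simultaneously above chance and significant at α = 0.001. Whether the
count rule and the α threshold are meant to be coupled exactly this way is
not spelled out in the source protocol; both are arguments of
`eligibility_check()`.

### Importance maps

For one condition, per-voxel importance is the product of the classifier
weight and the z-scored mean activation during that condition. Two readings
of "z-scored average activation" are possible; we z-score the
condition-mean activation vector *across voxels* (default), which makes the
map a weight-times-relative-topography product, and expose the alternative
(z-score each voxel over time, then average) behind
`zscore_over = "time"`. Thresholding flags voxels beyond `k_sd = 2`
*population* SDs from the within-map mean. A zero-centered cutoff is also
defensible; mean-centering is the conventional reading and the center is an
argument. Group `importance_frequency_map()`s require a shared voxel grid —
trivially true for synthetic cohorts, and for real data this means spatial
normalization upstream, which is deliberately out of scope here.

### Decoding and metrics

`decode_meditation()` reuses the 5-state model: probabilities are restricted
to {Breath, MW, Self} and renormalized, rather than retraining a 3-class
model. The decoded period is displayed and summarized over exactly these
three states, and reusing the Step-1 patterns keeps the decoder identical
to the validated classifier; retraining on three classes would change the
decision boundaries in ways Step 1 never validated. (Restriction is
equivalent to conditioning the softmax on the reduced state set; a 3-class
retrain remains an easy extension since `train_state_classifier()` accepts
any label subset.) Argmax ties are broken by the fixed state order
Breath < MW < Self and logged; they have measure zero on continuous data
and arise only in synthetic corner cases.

Mental events are maximal runs of ≥ 3 identical decisions (`min_len`
configurable); shorter runs remain unassigned. Attention metrics per state:
`percent_time` = share of *all* decided TRs (the three values sum to 100%),
event count, and mean/sample-SD of event durations in seconds. An
`events_only = TRUE` variant restricts the numerator to event-assigned TRs,
since "time spent engaged" is ambiguous between the two; the default
follows the finest-grained reading (every TR carries a decision).
Percentage time is invariant to `tr_seconds`; durations scale linearly
with it.

Group statistics are classical: one-sample two-sided t-tests against
chance with Cohen's d = (mean − ref)/SD, paired t-tests for breath-vs-other
occupancy, and Fisher r-to-Z (arctanh) transformation of within-subject
rating–accuracy Pearson correlations followed by a one-sample t-test
against 0. Per-trial accuracy for that correlation is the fraction of the
trial's TR decisions that are correct — the finest aggregation consistent
with trial-level ratings.

## The synthetic generator

`make_state_patterns()` draws each state's mean pattern as
`sqrt(overlap)·shared + sqrt(1−overlap)·unique` Gaussian components,
sparsified to the top `sparsity` fraction of magnitudes and scaled by
`amplitude`. `overlap = 0` gives uncorrelated patterns, `overlap = 1`
identical ones, with expected pairwise correlation monotone in between.

`build_ia_design()` reproduces the acquisition layout exactly: `n_blocks =
6` blocks; per block and condition, `per_condition_block_seconds = 72` s of
stimulus time split into 2–3 trials whose integer durations are drawn
uniformly from the feasible set of partitions with parts in `trial_bounds =
(16, 50)` s (infeasible bounds raise a configuration error); a 2-s
Instruction trial precedes every stimulus trial; conditions interleave
following one of four fixed cyclic-rotation order sets (the original
randomized order sets are not published, so a Latin-square-style stand-in
ships instead), rotated per block by the seed. At TR = 1 s this yields
exactly 432 labeled TRs per condition and 2160 in total. Attention ratings
(1–4) attach to the last half of non-MW trials; by default they are
uninformative noise, and `rating_coupling > 0` links them to realized trial
signal quality so the rating–accuracy association can be tested under both
the null and a positive alternative.

`simulate_ia_session()` adds i.i.d. Gaussian noise (`noise_sd`, drawn once
as standard normals and scaled, so different noise levels under one seed
are matched ladders) and optional per-voxel linear drift. **No hemodynamic
convolution is applied by default**: the boxcar signal keeps TR labels
exact, which is what makes ground truth exact for testing. Consequently the
default label lag is `lag_trs = 0`; for real BOLD data a 4–6 TR shift is
appropriate and is a plain argument of `extract_labeled_samples()`. An HRF
convolution could be layered on, but then ground-truth labels themselves
acquire a lag and every "exact" test becomes approximate — the design keeps
realism and exactness as separate switches.

`simulate_meditation_session()` evolves a hidden first-order Markov chain
over {Breath, MW, Self}, started from the chain's stationary distribution
(computed by eigen-decomposition). `stationary_transition_matrix(pi,
mean_dwell)` builds `P = (1−a)I + a·1πᵀ` with `a = 1/mean_dwell`: stay with
probability 1−a, otherwise resample from π. Its stationary distribution is
*exactly* π for every dwell setting (the resampling construction commutes
with π), at the cost that realized per-state dwell is `mean_dwell/(1−π_i)`
rather than uniform — a deliberate trade: occupancy recovery tests need the
stationary law exact far more than they need equal dwell times.

What the generator does **not** emulate: hemodynamic convolution (above),
temporally autocorrelated noise, physiological confounds (respiration,
cardiac cycles, head motion), scanner drift nonlinearity, and spatial
correlation between voxels. Passing tests therefore demonstrate the
*pipeline's* correctness — labeling, folding, fitting, thresholding,
decoding, segmenting, aggregating — under a clean signal model, not that
real fMRI sessions will decode at any particular accuracy.

## Calibration and problem sizes

No signal-to-noise figures exist for the real task, so synthetic SNR is an
explicit calibration, recorded in every manifest. The analysis cohort
(`analysis/00_settings.R`) uses 300 voxels, amplitude 1, sparsity 0.1, and
`noise_sd = 8`, chosen so single-TR cross-validated accuracy sits around
45–50% against 20% chance: substantially above chance, far below ceiling —
the regime TR-level fMRI decoding actually operates in. The test-suite and
acceptance-script checks choose sizes per purpose: noiseless exactness
checks at 40–150 voxels; chance-level (label-shuffled and zero-pattern)
checks on the full 2160-TR design at 300 voxels; percentage-time recovery
over 20 subjects at 200 voxels with `noise_sd = 1` (a high-SNR setting
where decoding error is negligible and the remaining deviation from the
planted 50/30/20 occupancy is chain sampling noise); the chi-square type-I
rate over 1000 simulated chance-level subjects; the event-segmentation
oracle over 10,000 random sequences.

## Numerical and degenerate-input rules

- TR indices are 0-based; a TR belongs to a trial iff its start time t
  satisfies `onset ≤ t < onset + duration` (half-open, no double counting).
- Constant voxels cannot be z-scored: they are set to all-zero and logged,
  never dropped, so voxel indices stay aligned for importance maps.
- A zero-variance importance map flags nothing (logged); a zero-variance
  rating or accuracy series yields a defined `NA` correlation (logged)
  rather than an error, so cohort aggregation can skip the subject; but
  zero variance *across subjects* in a group t-test is an error, because
  silently returning t = ∞ or 0 would misreport.
- Sample SD (n−1) everywhere a spread across observations is reported;
  population SD for the within-map importance threshold, where the map is
  the full population of voxel values being thresholded.
- All generators take explicit integer seeds and restore the caller's RNG
  state; pipeline stages derive child seeds from one root so runs are
  byte-reproducible end to end.

## Known limitations

Real-data preprocessing (motion correction, slice timing, registration) is
out of scope; `load_session()` expects preprocessed, mask-aligned NIfTI
input. Group frequency maps presuppose a shared grid, i.e. prior spatial
normalization for real cohorts. The importance-map thresholding identifies
each subject's most *extreme* voxels; alternatives that quantify per-voxel
influence directly (voxel-removal bootstraps, univariate effect sizes) are
documented extension points, not implemented. The demographics module
reproduces dual self-identified/standardized reporting arithmetic for
cohort description; its packaged example file is counts-faithful per axis
but synthetic in its row-level pairings.
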