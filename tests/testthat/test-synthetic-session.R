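test_that("state patterns respect overlap, sparsity, and seeding", {
  p1 <- make_state_patterns(100, overlap = 1, seed = 3)
  for (s in 2:5)
    expect_equal(p1$patterns[s, ], p1$patterns[1, ])

  a <- make_state_patterns(200, overlap = 0.4, seed = 11)
  b <- make_state_patterns(200, overlap = 0.4, seed = 11)
  expect_identical(a$patterns, b$patterns)

  k <- rowSums(a$patterns != 0)
  expect_true(all(k == round(0.1 * 200)))

  expect_error(make_state_patterns(3), "at least")
  expect_error(make_state_patterns(100, overlap = 2), "overlap")
})

test_that("pattern correlation is near zero without overlap and grows with it", {
  mean_abs_cor <- function(overlap, seeds) {
    mean(vapply(seeds, function(s) {
      m <- make_state_patterns(2000, overlap = overlap, seed = s)$patterns
      cm <- stats::cor(t(m))
      mean(abs(cm[upper.tri(cm)]))
    }, numeric(1)))
  }
  r0 <- mean_abs_cor(0, 1:30)
  r5 <- mean_abs_cor(0.5, 1:30)
  expect_lt(r0, 0.1)
  expect_gt(r5, r0)
  expect_gt(mean_abs_cor(1, 1:3), 0.999)
})

test_that("generated designs satisfy the block-budget invariants", {
  for (seed in 1:8) {
    d <- build_ia_design(seed = seed)
    expect_silent(validate_ia_design(d, check_budget = TRUE))
    stim <- d$trials[d$trials$condition != "Instruction", ]
    expect_true(all(stim$duration >= 16 & stim$duration <= 50))
  }
  d1 <- build_ia_design(n_blocks = 1, seed = 2)
  stim1 <- d1$trials[d1$trials$condition != "Instruction", ]
  expect_equal(sum(stim1$duration), 360)
  expect_equal(as.numeric(tapply(stim1$duration,
                                 as.character(stim1$condition), sum)),
               rep(72, 5))

  expect_error(build_ia_design(trial_bounds = c(40, 50)), "no partition")
})

test_that("IA simulation plants exact patterns under zero noise", {
  sess <- small_session(n_voxels = 40, noise_sd = 0, seed = 6)
  br <- sess$samples$features[sess$samples$labels == "Breath", ,
                              drop = FALSE]
  for (i in seq_len(nrow(br)))
    expect_equal(unname(br[i, ]), unname(sess$patterns$patterns["Breath", ]))

  again <- small_session(n_voxels = 40, noise_sd = 0, seed = 6)
  expect_identical(sess$ts$data, again$ts$data)

  expect_error(
    simulate_ia_session(sess$patterns, sess$design, noise_sd = -1),
    "noise_sd")
})

test_that("simulated noise has the configured scale", {
  pat <- make_state_patterns(500, seed = 9)
  design <- build_ia_design(n_blocks = 1, seed = 9)
  sess <- simulate_ia_session(pat, design, noise_sd = 1, seed = 10)
  samp <- extract_labeled_samples(sess$ts, sess$design)
  rows <- samp$labels == "MW"
  resid <- sweep(samp$features[rows, ], 2, pat$patterns["MW", ])
  sds <- apply(resid, 2, stats::sd)
  expect_lt(abs(mean(sds) - 1), 0.1)
})

test_that("meditation simulation follows the hidden Markov chain", {
  pat <- make_state_patterns(20, seed = 2)
  P <- stationary_transition_matrix(c(0.5, 0.3, 0.2), 10)
  med <- simulate_meditation_session(pat, P, duration_trs = 600,
                                     noise_sd = 1, seed = 3)
  expect_equal(nrow(med$ts$data), 600)
  expect_length(med$truth$state_sequence, 600)

  # chain absorbing into Breath from every state: truth is all Breath
  absorbing <- matrix(c(1, 0, 0), 3, 3, byrow = TRUE,
                      dimnames = list(meditation_states(),
                                      meditation_states()))
  abs_med <- simulate_meditation_session(pat, absorbing, duration_trs = 50,
                                         noise_sd = 0, seed = 4)
  expect_true(all(abs_med$truth$state_sequence == "Breath"))
  expect_equal(unname(abs_med$ts$data[7, ]),
               unname(pat$patterns["Breath", ]))

  bad <- matrix(1, 3, 3)
  expect_error(simulate_meditation_session(pat, bad), "sum to 1")
})

test_that("long chains converge to the eigen-decomposition stationary law", {
  pat <- make_state_patterns(5, seed = 1)
  # uniform symmetric chain: stationary = 1/3 each by symmetry
  Pu <- stationary_transition_matrix(rep(1 / 3, 3), 5)
  medu <- simulate_meditation_session(pat, Pu, duration_trs = 60000,
                                      noise_sd = 0, seed = 8)
  frac <- table(medu$truth$state_sequence) / 60000
  expect_true(all(abs(frac - 1 / 3) < 0.02))

  # skewed chain against an independent eigen oracle
  Ps <- stationary_transition_matrix(c(0.6, 0.25, 0.15), 8)
  meds <- simulate_meditation_session(pat, Ps, duration_trs = 30000,
                                      noise_sd = 0, seed = 9)
  ev <- eigen(t(Ps))
  target <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  target <- target / sum(target)
  fr <- as.numeric(table(meds$truth$state_sequence) / 30000)
  expect_true(all(abs(fr - target) < 0.03))
})

test_that("prescribed-stationary transition matrices are exact", {
  for (pi0 in list(c(0.5, 0.3, 0.2), c(1, 1, 1) / 3, c(0.7, 0.2, 0.1))) {
    P <- stationary_transition_matrix(pi0, 12)
    expect_equal(rowSums(P), rep(1, 3), ignore_attr = TRUE)
    expect_equal(as.numeric(pi0 %*% P), pi0)
  }
})
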