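test_that("the classifier separates noiseless patterns and yields proper probabilities", {
  fx <- synthetic_samples(n_per_state = 10, n_voxels = 40, noise_sd = 0)
  clf <- train_state_classifier(fx$samples)
  pr <- predict_state_probs(clf, fx$samples$features)
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-9)
  dec <- colnames(pr)[apply(pr, 1, which.max)]
  expect_equal(mean(dec == as.character(fx$samples$labels)), 1)

  # probabilities normalize for arbitrary inputs too
  pr1 <- predict_state_probs(clf, stats::rnorm(40))
  expect_equal(sum(pr1), 1, tolerance = 1e-9)

  one <- labeled_samples(matrix(stats::rnorm(20), 10, 2),
                         rep("Breath", 10), rep(1:2, 5),
                         paste0("t", 1:10))
  expect_error(train_state_classifier(one), "2 distinct")
})

test_that("training is invariant to sample order", {
  fx <- synthetic_samples(n_per_state = 30, n_voxels = 25, noise_sd = 1,
                          seed = 7)
  s <- fx$samples
  perm <- withr::with_seed(1, sample(nrow(s$features)))
  shuffled <- labeled_samples(s$features[perm, ], s$labels[perm],
                              s$blocks[perm], s$trial_ids[perm])
  p_orig <- predict_state_probs(train_state_classifier(s), s$features)
  p_shuf <- predict_state_probs(train_state_classifier(shuffled), s$features)
  expect_equal(p_orig, p_shuf, tolerance = 1e-8)
})

test_that("leave-one-block-out folds predict every sample exactly once", {
  sess <- small_session(n_voxels = 50, noise_sd = 0, seed = 3)
  rep0 <- crossvalidate_by_block(sess$samples)
  expect_equal(unname(rep0$per_condition_accuracy), rep(1, 5))
  expect_true(rep0$eligible)
  # exact partition: one prediction per sample, none missing
  expect_equal(nrow(rep0$predictions), nrow(sess$samples$features))
  expect_false(anyNA(rep0$predictions$predicted))
  expect_equal(sort(rep0$predictions$sample),
               seq_len(nrow(sess$samples$features)))
  expect_equal(unname(rowSums(rep0$confusion_matrix)),
               unname(as.numeric(rep0$n_per_condition)))

  one_block <- labeled_samples(sess$samples$features, sess$samples$labels,
                               rep(1L, nrow(sess$samples$features)),
                               sess$samples$trial_ids)
  expect_error(crossvalidate_by_block(one_block), ">= 2 blocks")
})

test_that("accuracy declines monotonically along a matched-noise ladder", {
  acc <- vapply(c(0, 1, 4, 16), function(ns) {
    sess <- small_session(n_voxels = 60, noise_sd = ns, seed = 21)
    mean(crossvalidate_by_block(sess$samples)$per_condition_accuracy)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
  expect_equal(acc[1], 1)
  expect_lt(acc[4], 0.45)
})

test_that("chi-square against chance matches hand arithmetic", {
  at_double <- accuracy_vs_chance_chisq(216, 432, 0.2)
  expect_equal(at_double$chisq, 243.0)
  expect_lt(at_double$p, 1e-15)

  near_null <- accuracy_vs_chance_chisq(86, 432, 0.2)
  expect_equal(near_null$chisq, 0.0023148, tolerance = 1e-4)
  expect_equal(near_null$p, 0.9616, tolerance = 1e-3)

  expect_error(accuracy_vs_chance_chisq(1, 0, 0.2), "n_total")
  expect_error(accuracy_vs_chance_chisq(1, 10, 0), "chance")
  expect_error(accuracy_vs_chance_chisq(11, 10, 0.2), "n_correct")
})

test_that("eligibility requires 2 of 3 meditation states above chance", {
  acc_hi <- c(0.5, 0.5, 0.5, 0.5, 0.5)
  expect_true(eligibility_check(
    fake_report(acc_hi, c(1e-5, 1e-9, 0.5, 1e-4, 0.9))))
  expect_false(eligibility_check(
    fake_report(acc_hi, c(1e-5, 1e-9, 0.5, 0.5, 0.9))))
  expect_true(eligibility_check(
    fake_report(acc_hi, c(1e-7, 1e-9, 1e-8, 0.5, 0.9))))
  # above-chance is required jointly with significance
  below <- c(0.1, 0.1, 0.5, 0.1, 0.5)
  expect_false(eligibility_check(
    fake_report(below, c(1e-9, 1e-9, 0.5, 1e-9, 0.9))))
  broken <- fake_report(c(NA, 0.5, 0.5, 0.5, 0.5), rep(1e-5, 5))
  expect_error(eligibility_check(broken), "Breath/MW/Self")
})

test_that("rating-accuracy association reproduces a hand Pearson computation", {
  a <- c(0.2, 0.5, 0.8, 1.0); r <- 1:4
  # independent oracle: covariance formula written out
  num <- sum((a - mean(a)) * (r - mean(r)))
  den <- sqrt(sum((a - mean(a))^2) * sum((r - mean(r))^2))
  got <- rating_accuracy_association(a, r)
  expect_equal(got$r, num / den, tolerance = 1e-12)
  expect_equal(got$r, 0.99591, tolerance = 1e-5)
  expect_equal(got$n_trials, 4)

  expect_message(
    flat <- rating_accuracy_association(a, c(3, 3, 3, 3)),
    "zero variance")
  expect_true(is.na(flat$r))

  rescaled <- rating_accuracy_association((1:4) / 4, 1:4)
  expect_equal(rescaled$r, 1)

  expect_error(rating_accuracy_association(a, 1:3), "equal length")
  expect_error(rating_accuracy_association(a[1:2], r[1:2]), "at least 3")
})

test_that("per-trial accuracies aggregate cross-validated TR decisions", {
  sess <- small_session(n_voxels = 50, noise_sd = 0, seed = 12)
  rep0 <- crossvalidate_by_block(sess$samples)
  ta <- trial_accuracy(rep0)
  stim <- sess$design$trials[sess$design$trials$condition != "Instruction", ]
  expect_equal(nrow(ta), nrow(stim))
  expect_equal(sum(ta$n_trs), nrow(sess$samples$features))
  expect_true(all(ta$accuracy == 1))  # noiseless: every TR correct
})
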