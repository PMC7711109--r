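test_that("attention metrics summarize decisions and event durations", {
  dec <- fake_decoded(rep(c("Breath", "MW", "Self"), times = c(300, 200, 100)))
  met <- compute_attention_metrics(dec)
  expect_equal(met$percent_time, c(50, 100 / 3, 100 / 6), tolerance = 1e-9)
  expect_equal(sum(met$percent_time), 100, tolerance = 1e-9)

  # two Breath events of 3 and 4 TRs, one long Self tail
  d2 <- fake_decoded(c("Breath", "Breath", "Breath", "MW", "MW",
                       "Breath", "Breath", "Breath", "Breath",
                       rep("Self", 6)))
  ev2 <- segment_mental_events(d2)
  m2 <- compute_attention_metrics(d2, ev2)
  b <- m2[m2$state == "Breath", ]
  expect_equal(b$n_events, 2)
  expect_equal(b$mean_duration_s, 3.5)
  expect_equal(b$sd_duration_s, 0.7071, tolerance = 1e-4)
  s <- m2[m2$state == "Self", ]
  expect_equal(s$n_events, 1)
  expect_true(is.na(s$sd_duration_s))  # sample SD undefined for one event
  mw <- m2[m2$state == "MW", ]
  expect_equal(mw$n_events, 0)         # 2-TR run is below min_len
  expect_equal(mw$percent_time, 100 * 2 / 15)

  bad_ev <- ev2
  bad_ev$onset_tr[1] <- 3  # shifted onto the MW run
  expect_error(compute_attention_metrics(d2, bad_ev), "do not match")
})

test_that("percent time ignores TR duration while durations scale with it", {
  decs <- rep(c("Breath", "MW"), times = c(9, 6))
  m1 <- compute_attention_metrics(fake_decoded(decs, tr_seconds = 1))
  m2 <- compute_attention_metrics(fake_decoded(decs, tr_seconds = 2))
  expect_equal(m1$percent_time, m2$percent_time)
  expect_equal(m2$mean_duration_s[1:2], 2 * m1$mean_duration_s[1:2])
})

test_that("events-only percent time counts event-assigned TRs", {
  d <- fake_decoded(c("Breath", "Breath", "Breath", "MW", "MW", "Self"))
  m <- compute_attention_metrics(d, events_only = TRUE)
  expect_equal(m$percent_time[m$state == "Breath"], 50)
  expect_equal(m$percent_time[m$state == "MW"], 0)
  expect_equal(m$percent_time[m$state == "Self"], 0)
})

test_that("group one-sample t-tests match hand and textbook computations", {
  gs <- group_accuracy_ttest(c(30, 40, 50), 20)
  expect_equal(gs$t, 3.4641, tolerance = 1e-4)
  expect_equal(gs$df, 2)
  expect_equal(gs$cohens_d, 2.0)
  expect_equal(gs$estimate, 40)

  flat <- group_accuracy_ttest(c(21, 19), 20)
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  expect_equal(flat$cohens_d, 0)

  expect_error(group_accuracy_ttest(c(20, 20, 20), 20), "zero variance")
  expect_error(group_accuracy_ttest(30, 20), "n >= 2")

  # textbook formula oracle on random draws
  withr::with_seed(5, {
    for (i in 1:20) {
      v <- stats::rnorm(sample(3:12, 1), mean = 25, sd = 5)
      got <- group_accuracy_ttest(v, 20)
      t_hand <- (mean(v) - 20) / (stats::sd(v) / sqrt(length(v)))
      p_hand <- 2 * stats::pt(-abs(t_hand), df = length(v) - 1)
      expect_equal(got$t, t_hand, tolerance = 1e-10)
      expect_equal(got$p, p_hand, tolerance = 1e-10)
    }
  })
})

test_that("Fisher r-to-Z group tests transform then t-test", {
  gs <- fisher_z_group_test(c(0.5, 0, -0.5))
  expect_equal(gs$estimate, 0)
  expect_equal(gs$t, 0)
  expect_equal(gs$p, 1)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)

  expect_error(fisher_z_group_test(c(0, 0, 0)), "zero variance")
  expect_error(fisher_z_group_test(0.9), "n >= 2")
  expect_error(fisher_z_group_test(c(0.5, 1)), "infinite")
  expect_message(ok <- fisher_z_group_test(c(0.5, -0.2, NA, 0.1)),
                 "excluding 1")
  expect_equal(ok$n, 3)
})

test_that("breath-vs-other comparisons are paired t-tests on differences", {
  mk <- function(id, b, mw, self) {
    data.frame(subject_id = id, state = c("Breath", "MW", "Self"),
               percent_time = c(b, mw, self), n_events = 1,
               mean_duration_s = 1, sd_duration_s = NA)
  }
  two <- rbind(mk("s1", 60, 20, 20), mk("s2", 50, 30, 20))
  gs <- compare_breath_vs_other(two, "MW")
  expect_equal(gs$estimate, 30)
  expect_equal(gs$t, 3.0, tolerance = 1e-9)
  expect_equal(gs$df, 1)

  same <- rbind(mk("s1", 40, 40, 20), mk("s2", 35, 35, 30))
  expect_error(compare_breath_vs_other(same, "MW"), "zero variance")

  sym <- rbind(mk("s1", 50, 40, 10), mk("s2", 30, 40, 30),
               mk("s3", 40, 40, 20))
  gs0 <- compare_breath_vs_other(sym, "MW")
  expect_equal(gs0$estimate, 0)
  expect_equal(gs0$t, 0)

  missing_pair <- rbind(mk("s1", 50, 40, 10)[1:2, ], mk("s2", 30, 20, 50))
  expect_error(compare_breath_vs_other(missing_pair, "Self"), "paired")
})

test_that("truth agreement is the per-TR match fraction", {
  P <- stationary_transition_matrix(rep(1 / 3, 3), 5)
  s <- rep(c("Breath", "MW"), 5)
  truth_same <- meditation_truth(s, P)
  expect_equal(sequence_recovery_score(fake_decoded(s), truth_same), 1)
  flipped <- rep(c("Self", "Breath"), 5)
  expect_equal(sequence_recovery_score(fake_decoded(flipped), truth_same), 0)

  withr::with_seed(77, {
    n <- 6000
    guess <- sample(meditation_states(), n, replace = TRUE)
    truth <- meditation_truth(sample(meditation_states(), n, replace = TRUE),
                              P)
    score <- sequence_recovery_score(fake_decoded(guess), truth)
    expect_lt(abs(score - 1 / 3), 0.025)
  })

  short <- meditation_truth(rep("Breath", 3), P)
  expect_error(sequence_recovery_score(fake_decoded(s), short), "length")
})
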