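test_that("win-stay and lose-shift match hand counts and degenerate agents", {
  ds <- toy_dataset(c(1, 1, 2, 2, 2), c(1, 0, 0, 1, 1))
  expect_equal(win_stay(ds), 1.0)    # 2 of 2 rewarded trials stayed
  expect_equal(lose_shift(ds), 0.5)  # 1 of 2 losses shifted

  stay <- toy_dataset(rep(1, 30), rep(c(1, 0), 15))
  expect_equal(win_stay(stay), 1)
  expect_equal(lose_shift(stay), 0)

  alt <- toy_dataset(rep(c(1, 2), 15), rep(c(1, 0), 15))
  expect_equal(win_stay(alt), 0)
  expect_equal(lose_shift(alt), 1)

  none <- toy_dataset(c(1, 2), c(0, 0))
  expect_warning(expect_true(is.na(win_stay(none))), "no eligible")
})

test_that("invalid trials break win-stay eligibility chains", {
  ds <- toy_dataset(c(1, 1, 1, 1), c(1, 1, 1, 1),
                    valid = c(TRUE, FALSE, TRUE, TRUE))
  # eligible pairs: only (3,4)
  expect_equal(win_stay(ds), 1)
  ds2 <- toy_dataset(c(1, 2, 1, 2), c(1, 1, 1, 1),
                     valid = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(win_stay(ds2), 0)
})

test_that("lag-1 autocorrelation follows the printed formula", {
  alt <- toy_dataset(rep(c(1, 2), 500), rep(0, 1000))
  expect_equal(lag1_autocorrelation(alt), -1, tolerance = 0.01)
  const <- toy_dataset(rep(1, 20), rep(0, 20))
  expect_warning(expect_true(is.na(lag1_autocorrelation(const))), "constant")
  set.seed(5)
  rand <- toy_dataset(sample(1:3, 1e4, replace = TRUE), rep(0, 1e4))
  expect_lt(abs(lag1_autocorrelation(rand)), 0.05)
  # oracle: direct formula on a small sequence
  x <- c(1, 3, 2, 2, 1, 3, 3, 2)
  ds <- toy_dataset(x, rep(0, 8))
  xb <- mean(x)
  r_oracle <- sum((x[-8] - xb) * (x[-1] - xb)) / sum((x - xb)^2)
  expect_equal(lag1_autocorrelation(ds), r_oracle, tolerance = 1e-12)
})

test_that("best-option rate credits maxima and splits ties", {
  sch <- flat_schedule(c(0.8, 0.2, 0.2), 10)
  oracle <- toy_dataset(rep(1, 10), rep(1, 10))
  oracle$schedule <- sch
  expect_equal(best_option_rate(oracle), 1)
  tied <- flat_schedule(c(0.5, 0.5, 0.5), 10)
  ds <- toy_dataset(c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1), rep(0, 10))
  ds$schedule <- tied
  expect_equal(best_option_rate(ds), 1 / 3)
  expect_error(best_option_rate(toy_dataset(1:3 * 0 + 1, rep(0, 3))),
               "schedule")
  # a uniform random agent sits at the 1/3 chance level
  sch2 <- generate_reward_schedule(5000, 3, seed = 17)
  rnd <- random_policy_dataset(sch2, seed = 18)
  expect_lt(abs(best_option_rate(rnd) - 1 / 3), 0.03)
})

test_that("reward sensitivity recovers constructed correlations", {
  sch <- flat_schedule(c(0.2, 0.5, 0.8), 100)
  prop <- toy_dataset(rep(c(1, 2, 2, 3, 3, 3), length.out = 96), rep(0, 96))
  prop$schedule <- flat_schedule(c(0.2, 0.5, 0.8), 96)
  expect_gt(reward_sensitivity(prop), 0.9)
  anti <- toy_dataset(rep(c(3, 2, 2, 1, 1, 1), length.out = 96), rep(0, 96))
  anti$schedule <- flat_schedule(c(0.2, 0.5, 0.8), 96)
  expect_lt(reward_sensitivity(anti), -0.9)
  unif <- toy_dataset(rep(c(1, 2, 3), 32), rep(0, 96))
  unif$schedule <- flat_schedule(c(0.2, 0.5, 0.8), 96)
  expect_warning(expect_true(is.na(reward_sensitivity(unif))), "degenerate")
})

test_that("individualized chance level and binomial test are exact", {
  ds <- toy_dataset(rep(1, 10), rep(0, 10))
  ds$schedule <- flat_schedule(c(0.5, 0.5, 0.5), 10)
  expect_equal(chance_level_test(ds)$chance, 0.5)
  ds$schedule <- flat_schedule(c(0.2, 0.5, 0.8), 10)
  expect_equal(chance_level_test(ds)$chance, 0.5)

  big <- toy_dataset(rep(1, 200), c(rep(1, 120), rep(0, 80)))
  big$schedule <- flat_schedule(c(0.5, 0.5, 0.5), 200)
  res <- chance_level_test(big)
  expect_equal(res$reward_count, 120)
  # oracle: explicit binomial tail sum
  tail_oracle <- sum(dbinom(120:200, 200, 0.5))
  expect_equal(res$p_value, tail_oracle, tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)
})

test_that("binned dynamics agree with an independent split-then-score oracle", {
  ds <- sim_vkf_subject(seed = 13, n_trials = 200)
  ds$schedule <- NULL
  dyn <- binned_dynamics(ds)
  expect_equal(nrow(dyn$bins), 20)
  for (b in c(1, 7, 20)) {
    sub <- ds
    sub$trials <- ds$trials[ds$trials$trial %in% ((b - 1) * 10 + 1):(b * 10), ]
    expect_equal(dyn$bins$win_stay[b], suppressWarnings(win_stay(sub)))
    expect_equal(dyn$bins$lose_shift[b], suppressWarnings(lose_shift(sub)))
  }
  expect_equal(dyn$phases$first, c(1, 51, 151))
  expect_equal(dyn$phases$last, c(50, 100, 200))

  stay <- toy_dataset(rep(1, 200), rep(1, 200))
  dyn2 <- binned_dynamics(stay)
  expect_true(all(dyn2$bins$win_stay == 1, na.rm = TRUE))
})

test_that("metric reports stay within range and relabeling invariance holds", {
  ds <- sim_vkf_subject(seed = 19)
  rep1 <- compute_metrics(ds)
  rates <- unlist(rep1[c("win_stay", "lose_shift", "best_option_rate")])
  expect_true(all(rates >= 0 & rates <= 1))
  expect_true(abs(rep1$lag1_autocorr) <= 1)

  # swap arm labels 1 <-> 2 everywhere: all metrics except lag-1 invariant
  ds2 <- ds
  ds2$trials$choice <- c(2, 1, 3)[ds$trials$choice]
  ds2$schedule$probs <- ds$schedule$probs[, c(2, 1, 3)]
  rep2 <- compute_metrics(ds2)
  for (m in c("win_stay", "lose_shift", "best_option_rate",
              "reward_sensitivity_r", "chance_level", "above_chance_p")) {
    expect_equal(rep2[[m]], rep1[[m]], tolerance = 1e-12, label = m)
  }
})
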