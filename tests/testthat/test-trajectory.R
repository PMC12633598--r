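test_that("linear slope matches exact and noisy constructions", {
  x <- 1:100
  y <- 2 - 0.01 * x
  ls <- linear_slope(y, x)
  expect_equal(ls$slope, -0.01, tolerance = 1e-12)
  expect_equal(ls$intercept, 2, tolerance = 1e-10)
  expect_lt(ls$p_value, 1e-10)

  const <- linear_slope(rep(3, 20), 1:20)
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_error(linear_slope(c(1, 2), 1:2), "3 points")
})

test_that("slope estimator has nominal coverage on noisy lines", {
  set.seed(9)
  cover <- vapply(1:200, function(i) {
    x <- 1:200
    y <- 1 - 0.005 * x + rnorm(200, 0, 0.2)
    ls <- linear_slope(y, x)
    abs(ls$slope - (-0.005)) <= 2 * ls$se
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("exponential fit recovers noiseless curves of both signs", {
  x <- 1:200
  for (b_true in c(-0.01, 0.004)) {
    y <- 2 * exp(b_true * x)
    ef <- exponential_fit(y, x)
    expect_equal(ef$a, 2, tolerance = 1e-6)
    expect_equal(ef$b, b_true, tolerance = 1e-6)
    if (b_true < 0) {
      expect_equal(ef$tau, -1 / b_true, tolerance = 1e-4)
    } else {
      expect_true(is.na(ef$tau))
    }
  }
  # after one time constant the curve is at 1/e (~37%) of its start
  ef <- exponential_fit(2 * exp(-0.01 * x), x)
  f0 <- ef$a * exp(ef$b * 0)
  f_tau <- ef$a * exp(ef$b * ef$tau)
  expect_equal(f_tau / f0, exp(-1), tolerance = 1e-6)
})

test_that("exponential rate survives multiplicative noise", {
  set.seed(21)
  bs <- vapply(1:100, function(i) {
    x <- 1:200
    y <- 2 * exp(-0.01 * x) * exp(rnorm(200, 0, 0.05))
    exponential_fit(y, x)$b
  }, numeric(1))
  expect_true(all(abs(bs - (-0.01)) / 0.01 < 0.2))
})

test_that("trajectory classification follows the rule table", {
  expect_equal(classify_trajectory(-0.005, 0.001), "decay")
  expect_equal(classify_trajectory(0.005, 0.001), "growth")
  expect_equal(classify_trajectory(0, 0.5), "flat")
  expect_equal(classify_trajectory(-0.005, 0.5, require_significance = TRUE),
               "flat")
  expect_equal(classify_trajectory(-0.005, 0.01, require_significance = TRUE),
               "decay")
  expect_equal(classify_trajectory(0.005, 0.2, require_significance = TRUE),
               "flat")
  expect_true(is.na(classify_trajectory(NA)))
})

test_that("decay proportion approaches one as noise vanishes", {
  set.seed(33)
  classes <- vapply(1:50, function(i) {
    y <- 1.5 * exp(-0.008 * (1:150)) * exp(rnorm(150, 0, 0.01))
    ef <- exponential_fit(y)
    classify_trajectory(ef$b, ef$p_value)
  }, character(1))
  expect_equal(mean(classes == "decay"), 1)
})

test_that("adaptation index sign convention and construct validity", {
  dec <- 3 * exp(-0.01 * (1:100))
  expect_gt(adaptation_index(dec)$index, 0)
  expect_equal(adaptation_index(rep(2, 50))$index, 0, tolerance = 1e-12)
  expect_lt(adaptation_index(3 * exp(0.005 * (1:100)))$index, 0)
  # decay-rate variant
  expect_equal(adaptation_index(dec, method = "decay")$index, 0.01,
               tolerance = 1e-4)
  # index is positive for agents whose initial volatility starts far above
  # its operating level (uncertainty visibly resolves with experience)
  idx <- vapply(1:15, function(s) {
    ds <- sim_vkf_subject(seed = 400 + s, n_trials = 200,
                          pars = c(lambda = 0.05, v0 = 8, sigma2 = 0.8,
                                   beta_v = 5, beta_u = 0.5))
    adaptation_index(latent_series(attr(ds, "latent"), "uncertainty"))$index
  }, numeric(1))
  expect_gt(mean(idx > 0), 0.8)
})

test_that("latent series extraction follows the chosen arm", {
  ds <- sim_vkf_subject(seed = 55, n_trials = 50)
  traj <- run_model(ds, "vkf", attr(ds, "params"))
  w_chosen <- latent_series(traj, "uncertainty")
  for (i in c(1, 20, 50)) {
    expect_equal(w_chosen[i],
                 traj[[paste0("w.arm", traj$choice[i])]][i])
  }
  k <- latent_series(traj, "learning_rate")
  expect_equal(as.numeric(k), traj$k)
  w_mean <- latent_series(traj, "uncertainty", arm = "mean")
  expect_equal(as.numeric(w_mean),
               rowMeans(traj[, paste0("w.arm", 1:3)]))
})

test_that("group contrasts detect constructed differences and nulls", {
  make_fits <- function(b_hc, b_tmd, seed) {
    set.seed(seed)
    rbind(
      data.frame(subject_id = paste0("h", 1:10), group = "HC",
                 series = "uncertainty",
                 slope = rnorm(10, -0.01, 0.002), slope_p = 0.01,
                 a = 1, b = rnorm(10, b_hc, 0.002), tau = NA, b_p = 0.01,
                 r_squared = 0.5,
                 class = ifelse(rnorm(10, b_hc, 0.002) < 0, "decay", "growth"),
                 adaptation_index = 0.01),
      data.frame(subject_id = paste0("t", 1:10), group = "TMD",
                 series = "uncertainty",
                 slope = rnorm(10, 0, 0.002), slope_p = 0.5,
                 a = 1, b = rnorm(10, b_tmd, 0.002), tau = NA, b_p = 0.5,
                 r_squared = 0.5,
                 class = ifelse(rnorm(10, b_tmd, 0.002) < 0, "decay", "growth"),
                 adaptation_index = 0))
  }
  con <- group_trajectory_contrast(make_fits(-0.01, 0.001, 1))
  expect_lt(con$slope_test$p.value, 0.01)
  expect_lt(con$decay_rate_test$p.value, 0.01)

  null_fits <- make_fits(-0.005, -0.005, 2)
  null_fits$slope <- rnorm(20, -0.005, 0.002)
  con0 <- group_trajectory_contrast(null_fits)
  expect_gt(con0$slope_test$p.value, 0.01)
})

test_that("Fisher's exact test matches exhaustive hypergeometric enumeration", {
  fisher_oracle <- function(tab) {
    # two-sided Fisher p: sum of probabilities of all tables with the same
    # margins whose probability does not exceed the observed table's
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    p_obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tabs <- list(matrix(c(9, 5, 2, 8), 2), matrix(c(1, 9, 9, 1), 2),
               matrix(c(0, 7, 12, 3), 2), matrix(c(4, 4, 4, 4), 2),
               matrix(c(13, 2, 1, 11), 2))
  for (tab in tabs) {
    expect_equal(stats::fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-10)
  }
  # sweep all small tables with margins <= 8
  for (m in 2:8) for (k in 1:(m - 1)) {
    tab <- matrix(c(k, m - k, m - k, k), 2)
    expect_equal(stats::fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-10)
  }
})
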