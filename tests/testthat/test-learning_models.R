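test_that("Rescorla-Wagner updates follow the delta rule", {
  st <- list(m = c(0, 0, 0))
  expect_equal(rw_update(st, 1, 1, c(alpha = 0.5))$m[1], 0.5)
  expect_equal(rw_update(st, 2, 1, c(alpha = 0))$m, c(0, 0, 0))
  expect_equal(rw_update(st, 3, 1, c(alpha = 1))$m[3], 1)
  st2 <- list(m = c(0.5, 0.5, 0.5))
  expect_equal(rw_update(st2, 1, 1,
                         c(alpha_pos = 0.4, alpha_neg = 0.1), "rw2")$m[1], 0.7)
  expect_equal(rw_update(st2, 1, 0,
                         c(alpha_pos = 0.4, alpha_neg = 0.1), "rw2")$m[1], 0.45)
  expect_error(rw_update(st, 1, 1, c(alpha = 1.5)), "learning rate")
  expect_error(rw_update(st, 1, 2, c(alpha = 0.5)), "outcome")
})

test_that("Kalman filter update matches hand arithmetic and limits", {
  st <- list(m = c(0, 0, 0), w = c(1, 1, 1))
  up <- kf_update(st, 1, 1, c(v = 0.5, sigma2 = 1))
  expect_equal(up$k, 0.6)
  expect_equal(up$m[1], 0.6)
  expect_equal(up$w[1], 0.6)
  expect_equal(up$w[2], 1.5)   # unchosen arms diffuse
  expect_equal(up$m[2], 0)

  # huge observation noise: no update
  up2 <- kf_update(st, 1, 1, c(v = 0.5, sigma2 = 1e9))
  expect_lt(up2$k, 1e-8)
  expect_lt(abs(up2$m[1]), 1e-8)

  # tiny process noise: posterior variance shrinks monotonically
  st3 <- list(m = c(0.5, 0.5, 0.5), w = c(1, 1, 1))
  ws <- numeric(50)
  for (i in 1:50) {
    st3 <- kf_update(st3, 1, i %% 2, c(v = 1e-12, sigma2 = 1))
    ws[i] <- st3$w[1]
  }
  expect_true(all(diff(ws) < 0))
  expect_error(kf_update(st, 1, 1, c(v = -1, sigma2 = 1)), "positive")
})

test_that("volatile Kalman filter update matches hand arithmetic", {
  st <- list(m = c(0.5, 0.5, 0.5), w = c(1, 1, 1), v = c(1, 1, 1))
  up <- vkf_update(st, 1, 1, c(lambda = 0.1, sigma2 = 1))
  expect_equal(up$k, 2 / 3, tolerance = 1e-10)
  expect_equal(up$m[1], 0.5 + (2 / 3) * 0.5, tolerance = 1e-10)
  expect_equal(up$w[1], 2 / 3, tolerance = 1e-10)
  expect_equal(up$v[1], 1 + 0.1 * (1 / 9), tolerance = 1e-10)
  expect_equal(up$w[2], 2)     # unchosen arms diffuse by their own volatility
  expect_equal(up$v[2], 1)
})

test_that("volatility stays positive over random update sequences", {
  set.seed(42)
  for (rep in 1:100) {
    pars <- c(lambda = runif(1), sigma2 = runif(1, 0.05, 3))
    st <- list(m = runif(3), w = runif(3, 0.05, 3), v = runif(3, 0.05, 3))
    for (t in 1:100) {
      st <- vkf_update(st, sample(3, 1), rbinom(1, 1, 0.5), pars)
      expect_true(all(st$v > 0))
      expect_true(st$k > 0 && st$k < 1)
    }
  }
})

test_that("VKF with lambda = 0 reduces to the constant-volatility KF", {
  ds <- sim_vkf_subject(seed = 3, n_trials = 150)
  v0 <- 2.5
  tr_vkf <- run_model(ds, "vkf", c(lambda = 0, v0 = v0, sigma2 = 0.8,
                                   beta_v = 3, beta_u = 1))
  tr_kf <- run_model(ds, "kf", c(v = v0, sigma2 = 0.8, beta_v = 3))
  expect_equal(unname(as.matrix(tr_vkf[, paste0("m.arm", 1:3)])),
               unname(as.matrix(tr_kf[, paste0("m.arm", 1:3)])),
               tolerance = 1e-12)
  expect_equal(unname(as.matrix(tr_vkf[, paste0("w.arm", 1:3)])),
               unname(as.matrix(tr_kf[, paste0("w.arm", 1:3)])),
               tolerance = 1e-12)
  expect_true(all(abs(tr_vkf$v.arm1 - v0) < 1e-12))
})

test_that("softmax is normalized, shift-invariant and matches closed forms", {
  p0 <- softmax_policy(c(5, 1, 3), beta_v = 0, beta_u = 0)
  expect_equal(p0, rep(1 / 3, 3))
  p1 <- softmax_policy(c(1, 0, 0), beta_v = 1, variant = "V")
  expect_equal(p1[1], exp(1) / (exp(1) + 2), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:50) {
    v <- rnorm(3, sd = 5); u <- rnorm(3, sd = 5)
    p <- softmax_policy(v, u, beta_v = 2, beta_u = 1)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(softmax_policy(v + 7.3, u, beta_v = 2, beta_u = 1), p,
                 tolerance = 1e-12)
    expect_true(all(p > 0))
  }
  # extreme values stay finite (overflow-safe)
  expect_equal(sum(softmax_policy(c(1e4, 0, -1e4), beta_v = 1, variant = "V")), 1)
})

test_that("relative transform normalizes positive quantities", {
  expect_equal(relative_transform(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_equal(relative_transform(c(2, 2, 2)), rep(1 / 3, 3))
  set.seed(2)
  for (i in 1:20) {
    x <- runif(3, 0.01, 10)
    expect_equal(sum(relative_transform(x)), 1, tolerance = 1e-12)
  }
  expect_error(relative_transform(c(1, -1, 1)), "positive")
})

test_that("run_model matches the agent's internal states bit for bit", {
  for (m in model_ids()) {
    pars <- switch(m,
      rw1 = c(alpha = 0.3, beta_v = 3),
      rw2 = c(alpha_pos = 0.4, alpha_neg = 0.2, beta_v = 3),
      kf = c(v = 0.5, sigma2 = 1, beta_v = 3),
      vkf = vkf_pars,
      vkf_rv = c(lambda = 0.2, v0 = 3, sigma2 = 0.8, beta_v = 3))
    sch <- generate_reward_schedule(120, 3, seed = 8)
    ds <- simulate_agent(sch, m, pars, seed = 9)
    traj <- run_model(ds, m, pars)
    lat <- attr(ds, "latent")
    shared <- intersect(names(traj), names(lat))
    expect_identical(as.matrix(traj[, shared]), as.matrix(lat[, shared]),
                     label = paste("round trip for", m))
    # fast NLL equals the trajectory log-likelihood
    expect_equal(negative_log_likelihood(ds, m, pars),
                 -attr(traj, "loglik"), tolerance = 1e-10)
  }
})

test_that("invalid trials are skipped without state updates", {
  ds <- toy_dataset(c(1, 2, NA, 3, 1), c(1, 0, NA, 1, 0),
                    rt = c(0.5, 0.5, 0.5, 6, 0.5))
  expect_equal(ds$trials$valid, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  traj <- run_model(ds, "rw1", c(alpha = 0.5, beta_v = 1))
  expect_equal(nrow(traj), 3)
  expect_equal(traj$trial, c(1, 2, 5))
  # same as filtering the valid-only dataset
  ds2 <- toy_dataset(c(1, 2, 1), c(1, 0, 0))
  traj2 <- run_model(ds2, "rw1", c(alpha = 0.5, beta_v = 1))
  expect_equal(traj$logp, traj2$logp)
})

test_that("negative log-likelihood has the closed uniform-policy form", {
  ds <- toy_dataset(rep(c(1, 2, 3), length.out = 200),
                    rep(c(0, 1), length.out = 200))
  nll <- negative_log_likelihood(ds, "vkf",
                                 c(lambda = 0.2, v0 = 3, sigma2 = 0.8,
                                   beta_v = 0, beta_u = 0))
  expect_equal(nll, 200 * log(3), tolerance = 1e-10)
  empty <- toy_dataset(c(NA, NA), c(NA, NA))
  expect_warning(z <- negative_log_likelihood(empty, "rw1",
                                              c(alpha = 0.5, beta_v = 1)),
                 "no valid trials")
  expect_equal(z, 0)
})

test_that("NLL at generating parameters beats strongly perturbed parameters", {
  set.seed(7)
  diffs <- vapply(1:20, function(s) {
    ds <- sim_vkf_subject(seed = s, n_trials = 150)
    pars <- attr(ds, "params")
    bad <- pars
    bad["beta_v"] <- pars[["beta_v"]] * 8
    bad["lambda"] <- min(0.99, pars[["lambda"]] * 4)
    negative_log_likelihood(ds, "vkf", bad) -
      negative_log_likelihood(ds, "vkf", pars)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
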