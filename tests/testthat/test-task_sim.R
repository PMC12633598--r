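test_that("schedule respects bounds, grid steps and determinism", {
  sch <- generate_reward_schedule(200, 3, seed = 11)
  expect_true(all(sch$probs >= 0.1 - 1e-12 & sch$probs <= 0.9 + 1e-12))
  for (a in 1:3) {
    d <- round(diff(sch$probs[, a]), 10)
    expect_true(all(d %in% c(0, 0.1, -0.1)))
  }
  expect_identical(generate_reward_schedule(200, 3, seed = 11)$probs, sch$probs)

  frozen <- generate_reward_schedule(50, 4, step_prob = 0, seed = 3)
  expect_true(all(apply(frozen$probs, 2, function(x) all(x == x[1]))))

  expect_error(generate_reward_schedule(0, 3), "n_trials")
  expect_error(generate_reward_schedule(10, 1), "n_arms")
  expect_error(generate_reward_schedule(10, 3, bounds = c(0.9, 0.1)), "bounds")
})

test_that("per-arm change frequency matches the step probability", {
  # Monte-Carlo over seeds; boundary rejections pull the rate slightly
  # below the nominal 10%
  rates <- vapply(1:120, function(s) {
    sch <- generate_reward_schedule(200, 3, step_prob = 0.1, seed = s)
    mean(diff(sch$probs) != 0)
  }, numeric(1))
  expect_gt(mean(rates), 0.07)
  expect_lt(mean(rates), 0.105)
})

test_that("interior-started change counts pass a binomial goodness-of-fit check", {
  # small steps keep the walk away from the bounds; only walks starting
  # well inside are scored, so no proposal is ever rejected
  counts <- unlist(lapply(1:120, function(s) {
    sch <- generate_reward_schedule(101, 3, step_prob = 0.1, step_size = 0.01,
                                    bounds = c(0.01, 0.99), seed = s)
    interior <- sch$probs[1, ] > 0.25 & sch$probs[1, ] < 0.75
    vapply(which(interior), function(a) sum(diff(sch$probs[, a]) != 0),
           numeric(1))
  }))
  expect_gt(length(counts), 100)
  p <- suppressWarnings(
    chisq.test(table(factor(pmin(counts, 25), levels = 0:25)),
               p = c(dbinom(0:24, 100, 0.1),
                     pbinom(24, 100, 0.1, lower.tail = FALSE)))$p.value)
  expect_gt(p, 0.01)
})

test_that("agent simulation is reproducible and honours its policy limits", {
  sch <- generate_reward_schedule(100, 3, seed = 5)
  a1 <- simulate_agent(sch, "vkf", vkf_pars, seed = 9)
  a2 <- simulate_agent(sch, "vkf", vkf_pars, seed = 9)
  expect_identical(a1$trials, a2$trials)
  expect_true(all(a1$trials$valid))
  expect_error(simulate_agent(sch, "nonsense", vkf_pars), "unknown model_id")

  # beta = 0 gives uniform choice frequencies
  unif <- simulate_agent(generate_reward_schedule(3000, 3, seed = 2), "vkf",
                         c(lambda = 0.2, v0 = 3, sigma2 = 0.8,
                           beta_v = 0, beta_u = 0), seed = 4)
  freq <- tabulate(unif$trials$choice, 3) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.05))

  # near-greedy value agent on a static schedule converges on the best arm
  sch_best <- flat_schedule(c(0.9, 0.1, 0.1), 500)
  greedy <- simulate_agent(sch_best, "vkf",
                           c(lambda = 0.1, v0 = 1, sigma2 = 0.5,
                             beta_v = 60, beta_u = 0), seed = 6)
  late <- greedy$trials$choice[301:500]
  expect_gt(mean(late == 1), 0.9)
})

test_that("reward-conditioned drift only moves after rewarded trials", {
  sch <- generate_reward_schedule(150, 3, seed = 41)
  ds <- simulate_agent(sch, "rw1", c(alpha = 0.3, beta_v = 2), seed = 42,
                       drift_on_reward = TRUE)
  p <- ds$schedule$probs
  oc <- ds$trials$outcome
  for (t in 1:149) {
    if (oc[t] == 0) expect_identical(p[t + 1, ], p[t, ])
  }
  expect_true(all(p >= 0.1 - 1e-12 & p <= 0.9 + 1e-12))
  # at least some rewarded trials do move the walk
  moved <- vapply(which(oc[1:149] == 1),
                  function(t) any(p[t + 1, ] != p[t, ]), logical(1))
  expect_gt(mean(moved), 0)
})

test_that("random policy matches chance statistics", {
  sch <- generate_reward_schedule(6000, 3, seed = 21)
  ds <- random_policy_dataset(sch, seed = 22)
  freq <- tabulate(ds$trials$choice, 3) / 6000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
  # expected reward rate is the schedule grand mean
  expect_lt(abs(mean(ds$trials$outcome) - mean(sch$probs)), 0.03)
})

test_that("cohort simulation realizes the configured two-group design", {
  spec <- cohort_spec(groups = default_groups(n_hc = 6, n_tmd = 6),
                      n_trials = 120, seed = 31)
  coh <- simulate_cohort(spec)
  expect_length(coh, 12)
  truth <- attr(coh, "truth")
  expect_setequal(unique(truth$group), c("HC", "TMD"))
  expect_true(all(vapply(coh, function(s) !is.null(s$scores), TRUE)))
  expect_true(all(vapply(coh, function(s) s$scores$vas >= 0 &&
                           s$scores$vas <= 100, TRUE)))
  expect_true(all(vapply(coh, function(s)
    s$scores$gcps %in% c("I", "II", "III", "IV"), TRUE)))
  # determinism
  coh2 <- simulate_cohort(spec)
  expect_identical(attr(coh2, "truth"), truth)
  expect_identical(coh2[[3]]$trials, coh[[3]]$trials)
})

test_that("identically configured groups show no systematic group difference", {
  # downstream statistic: t-test on true adaptation indices
  same <- default_groups(n_hc = 8, n_tmd = 8)
  same$TMD$dist <- same$HC$dist
  pvals <- vapply(1:12, function(s) {
    coh <- simulate_cohort(cohort_spec(groups = same, n_trials = 100, seed = s))
    tr <- attr(coh, "truth")
    group_ttest(tr$true_index[tr$group == "HC"],
                tr$true_index[tr$group == "TMD"])$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("default groups realize the adaptive vs impaired-adaptation phenotype", {
  coh <- simulate_cohort(cohort_spec(groups = default_groups(n_hc = 20,
                                                             n_tmd = 16),
                                     seed = 31))
  tr <- attr(coh, "truth")
  sl <- vapply(coh, function(ds)
    linear_slope(latent_series(attr(ds, "latent"), "uncertainty"))$slope,
    numeric(1))
  hc <- sl[tr$group == "HC"]; tmd <- sl[tr$group == "TMD"]
  # controls reduce uncertainty; the impaired group stays flat
  expect_lt(mean(hc), mean(tmd))
  expect_lt(mean(hc), 0)
  expect_lt(group_ttest(hc, tmd)$p_value, 0.01)
})

test_that("apathy scores inherit the mediation structure from the index", {
  spec <- cohort_spec(groups = default_groups(n_hc = 30, n_tmd = 30),
                      apathy_loading = -6, apathy_noise_sd = 2, seed = 77)
  spec$n_trials <- 150
  coh <- simulate_cohort(spec)
  truth <- attr(coh, "truth")
  sc <- cohort_scores(coh)
  sc <- sc[match(truth$subject_id, sc$subject_id), ]
  # negative loading: better adaptation, lower apathy
  expect_lt(cor(truth$true_index, sc$ami), 0)
  # group effect present
  expect_gt(mean(sc$ami[truth$group == "TMD"]),
            mean(sc$ami[truth$group == "HC"]))
})
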