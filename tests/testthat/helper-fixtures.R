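# Shared fixtures: tiny deterministic datasets built in code.

# dataset from explicit choice/outcome vectors, no schedule
toy_dataset <- function(choices, outcomes, n_arms = 3, valid = NULL,
                        rt = NULL) {
  n <- length(choices)
  trials <- data.frame(trial = seq_len(n), choice = choices,
                       outcome = outcomes,
                       rt = if (is.null(rt)) rep(0.5, n) else rt)
  if (!is.null(valid)) trials$valid <- valid
  subject_dataset(trials, n_arms = n_arms)
}

# constant-probability schedule (no drift)
flat_schedule <- function(probs_row, n_trials = 100) {
  sch <- generate_reward_schedule(n_trials, length(probs_row), step_prob = 0,
                                  seed = 1L)
  sch$probs <- matrix(probs_row, n_trials, length(probs_row), byrow = TRUE,
                      dimnames = list(NULL, paste0("arm", seq_along(probs_row))))
  sch
}

vkf_pars <- c(lambda = 0.2, v0 = 3, sigma2 = 0.8, beta_v = 3, beta_u = 1)

sim_vkf_subject <- function(seed = 1L, n_trials = 200, pars = vkf_pars) {
  sch <- generate_reward_schedule(n_trials, 3, seed = seed)
  simulate_agent(sch, "vkf", pars, seed = seed + 1L)
}
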