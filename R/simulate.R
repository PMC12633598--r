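# ---- subject datasets -------------------------------------------------------

#' Construct a subject dataset
#'
#' Bundles one subject's trial records with an optional reward schedule,
#' group label and questionnaire scores. Trials must be sorted by trial
#' index with no duplicates; a trial is invalid when the response is
#' missing or slower than `rt_cutoff` seconds, and outcomes are only
#' retained on valid trials.
#'
#' @param trials data frame with columns `trial`, `choice` (1-based arm or
#'   `NA`), `outcome` (0/1 or `NA`), and optionally `rt` (seconds) and
#'   `valid`.
#' @param n_arms number of arms.
#' @param subject_id identifier string.
#' @param group group label (e.g. `"HC"` or `"TMD"`).
#' @param schedule optional `reward_schedule`.
#' @param scores optional named list of questionnaire scores.
#' @param rt_cutoff response deadline in seconds used to mark slow trials
#'   invalid when no `valid` column is supplied.
#' @return an object of class `subject_dataset`.
#' @export
subject_dataset <- function(trials, n_arms, subject_id = "s1", group = NA_character_,
                            schedule = NULL, scores = NULL, rt_cutoff = 5) {
  need <- c("trial", "choice", "outcome")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("trials is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  trials <- as.data.frame(trials)
  if (is.null(trials$rt)) trials$rt <- NA_real_
  if (anyDuplicated(trials$trial)) stop("duplicate trial indices")
  trials <- trials[order(trials$trial), , drop = FALSE]
  if (is.null(trials$valid)) {
    trials$valid <- !is.na(trials$choice) &
      (is.na(trials$rt) | trials$rt <= rt_cutoff)
  }
  trials$valid <- trials$valid & !is.na(trials$choice)
  trials$outcome[!trials$valid] <- NA_real_
  if (!is.null(schedule)) {
    if (n_trials_of(schedule) < max(trials$trial)) {
      stop("schedule has fewer trials than the dataset")
    }
    if (n_arms_of(schedule) != n_arms) stop("schedule arm count mismatch")
  }
  structure(
    list(subject_id = subject_id, group = group, trials = trials,
         n_arms = as.integer(n_arms), schedule = schedule, scores = scores),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %s (%s): %d trials (%d valid), %d arms%s%s\n",
              x$subject_id, x$group, nrow(x$trials), sum(x$trials$valid),
              x$n_arms,
              if (!is.null(x$schedule)) ", schedule attached" else "",
              if (!is.null(x$scores)) ", scores attached" else ""))
  invisible(x)
}

n_valid_trials <- function(dataset) sum(dataset$trials$valid)

# plausible response times under the deadline; not a model of RT
sim_rts <- function(n) pmin(round(stats::rlnorm(n, log(0.8), 0.35), 3), 4.9)

# ---- agent simulation -------------------------------------------------------

#' Simulate an artificial subject on a reward schedule
#'
#' Plays a parameterized learning agent through every trial of a schedule:
#' at each trial the agent's softmax policy (computed from its pre-choice
#' latent state) samples a choice, the outcome is Bernoulli with the
#' scheduled reward probability of the chosen arm, and the agent's latent
#' state updates as in [run_model()]. All simulated trials are valid.
#'
#' @param schedule a `reward_schedule`.
#' @param model_id model identifier, see [model_ids()].
#' @param params named parameter vector for the model.
#' @param seed integer seed; the only source of randomness.
#' @param subject_id,group passed to the resulting dataset.
#' @param drift_on_reward when `TRUE`, the schedule's random walk only
#'   moves after rewarded trials (the probabilities are re-evolved online
#'   from the schedule's first row using its step settings); the default
#'   `FALSE` drifts on every trial as pre-generated.
#' @inheritParams run_model
#' @return a `subject_dataset` with the generating parameters in
#'   `attr(, "params")` and the agent's internal latent trajectory in
#'   `attr(, "latent")` (same layout as [run_model()] output).
#' @export
simulate_agent <- function(schedule, model_id, params, seed = 1L,
                           subject_id = "sim1", group = NA_character_,
                           m0 = 0.5, w0 = NULL, drift_on_reward = FALSE) {
  info <- model_info(model_id)
  params <- validate_params(model_id, params)
  n_trials <- n_trials_of(schedule)
  n_arms <- n_arms_of(schedule)
  arm_nm <- paste0("arm", seq_len(n_arms))

  res <- withr::with_seed(seed, {
    state <- init_state(model_id, params, n_arms, m0 = m0, w0 = w0)
    probs <- schedule$probs
    cur <- probs[1, ]
    choice <- integer(n_trials); outcome <- numeric(n_trials)
    M <- matrix(NA_real_, n_trials, n_arms)
    W <- matrix(NA_real_, n_trials, n_arms)
    V <- matrix(NA_real_, n_trials, n_arms)
    K <- rep(NA_real_, n_trials); RV <- rep(NA_real_, n_trials)
    RU <- rep(NA_real_, n_trials); LP <- rep(NA_real_, n_trials)
    for (t in seq_len(n_trials)) {
      if (drift_on_reward) probs[t, ] <- cur
      pol <- policy_of_state(state, model_id, params, info)
      ch <- sample.int(n_arms, 1L, prob = pol$p)
      oc <- as.numeric(stats::runif(1) < probs[t, ch])
      choice[t] <- ch; outcome[t] <- oc
      LP[t] <- log(pol$p[ch]); RV[t] <- pol$rv[ch]; RU[t] <- pol$ru[ch]
      state <- step_state(state, model_id, ch, oc, params)
      M[t, ] <- state$m
      if (!is.null(state$w)) W[t, ] <- state$w
      if (!is.null(state$v)) V[t, ] <- state$v
      if (!is.null(state$k)) K[t] <- state$k
      if (drift_on_reward && oc == 1) {
        move <- stats::runif(n_arms) < schedule$step_prob
        dir <- sample(c(-1, 1), n_arms, replace = TRUE)
        prop <- cur + ifelse(move, dir * schedule$step_size, 0)
        bad <- prop < schedule$bounds[1] - 1e-12 |
          prop > schedule$bounds[2] + 1e-12
        prop[bad] <- cur[bad]
        cur <- prop
      }
    }
    list(choice = choice, outcome = outcome, M = M, W = W, V = V,
         K = K, RV = RV, RU = RU, LP = LP, rt = sim_rts(n_trials),
         probs = probs)
  })

  if (drift_on_reward) schedule$probs <- res$probs
  trials <- data.frame(trial = seq_len(n_trials), choice = res$choice,
                       outcome = res$outcome, rt = res$rt, valid = TRUE)
  ds <- subject_dataset(trials, n_arms, subject_id = subject_id, group = group,
                        schedule = schedule)
  latent <- data.frame(trial = seq_len(n_trials), choice = res$choice,
                       outcome = res$outcome, k = res$K, rv = res$RV,
                       ru = res$RU, logp = res$LP)
  latent <- cbind(latent,
                  stats::setNames(as.data.frame(res$M), paste0("m.", arm_nm)))
  if (!all(is.na(res$W))) {
    latent <- cbind(latent,
                    stats::setNames(as.data.frame(res$W), paste0("w.", arm_nm)))
  }
  if (!all(is.na(res$V))) {
    latent <- cbind(latent,
                    stats::setNames(as.data.frame(res$V), paste0("v.", arm_nm)))
  }
  attr(ds, "params") <- params
  attr(ds, "model_id") <- model_id
  attr(ds, "latent") <- latent
  ds
}

#' Simulate a subject that chooses uniformly at random
#'
#' Reference non-learner: every choice is uniform over the arms and
#' outcomes are Bernoulli with the scheduled probability of the chosen
#' arm. Its long-run best-option rate is the 1/`n_arms` chance level
#' (33.3% for three arms) and its expected reward rate is the schedule's
#' grand mean probability.
#'
#' @inheritParams simulate_agent
#' @return a `subject_dataset`.
#' @export
random_policy_dataset <- function(schedule, seed = 1L, subject_id = "rand1",
                                  group = NA_character_) {
  n_trials <- n_trials_of(schedule)
  n_arms <- n_arms_of(schedule)
  res <- withr::with_seed(seed, {
    choice <- sample.int(n_arms, n_trials, replace = TRUE)
    p <- schedule$probs[cbind(seq_len(n_trials), choice)]
    outcome <- as.numeric(stats::runif(n_trials) < p)
    list(choice = choice, outcome = outcome, rt = sim_rts(n_trials))
  })
  trials <- data.frame(trial = seq_len(n_trials), choice = res$choice,
                       outcome = res$outcome, rt = res$rt, valid = TRUE)
  subject_dataset(trials, n_arms, subject_id = subject_id, group = group,
                  schedule = schedule)
}

# ---- cohort specification and simulation ------------------------------------

#' Transformed-space parameter distributions for agent sampling
#'
#' Each model parameter is drawn from a normal distribution in its
#' transformed (unconstrained) space: logit scale for unit-range
#' parameters, log scale for positive ones. Defaults give dispersed but
#' plausible agents: natively, `lambda` spans roughly 0.04-0.65, `v0`
#' roughly 0.04-6, `sigma2` roughly 0.05-19, `beta_v` roughly 0.3-16 and
#' `beta_u` roughly 0.8-6 (central 95% intervals). The `v0` location is
#' kept small relative to `sigma2` so that the Kalman gain does not
#' saturate and the observation-noise parameter stays behaviourally
#' identifiable; the uncertainty weight is drawn with a tighter dispersion
#' than the value weight.
#'
#' @param lambda,v0,sigma2,beta_v,beta_u length-2 `(location, scale)` pairs
#'   in transformed space.
#' @return named list of location/scale pairs.
#' @export
agent_param_dist <- function(lambda = c(stats::qlogis(0.2), 0.9),
                             v0 = c(log(0.5), 1.3),
                             sigma2 = c(log(1), 1.5),
                             beta_v = c(log(2.2), 1.0),
                             beta_u = c(log(2.2), 0.5)) {
  list(lambda = lambda, v0 = v0, sigma2 = sigma2,
       beta_v = beta_v, beta_u = beta_u)
}

draw_agent_params <- function(model_id, dist) {
  spec <- param_transform_spec(model_id)
  nm <- spec$name
  theta <- vapply(nm, function(p) {
    if (is.null(dist[[p]])) stop("no distribution for parameter ", p)
    stats::rnorm(1, dist[[p]][1], dist[[p]][2])
  }, numeric(1))
  theta_to_native(theta, spec)
}

#' Specify a synthetic two-group cohort
#'
#' Describes the study design the generator emulates: per-group subject
#' counts and agent-parameter distributions, the task settings, and a
#' linear structural model for questionnaire scores in which the group
#' effect on apathy is partially transmitted through each agent's
#' uncertainty-adaptation index (computed from the agent's own simulated
#' uncertainty trajectory and standardized across the cohort):
#' `AMI = base + group_effect * X + loading * z(index) + noise`.
#'
#' @param groups named list; each element has `n` (subject count),
#'   `dist` (an [agent_param_dist()]) and optionally `model_id`.
#' @param n_trials,n_arms,step_prob,step_size,bounds task settings.
#' @param apathy_base,apathy_group_effect,apathy_loading,apathy_noise_sd
#'   coefficients of the apathy-generating model; the second group listed
#'   receives `apathy_group_effect`, and `apathy_loading` multiplies the
#'   standardized adaptation index (negative: better adaptation, less
#'   apathy).
#' @param seed integer master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = default_groups(),
                        n_trials = 200, n_arms = 3,
                        step_prob = 0.1, step_size = 0.1, bounds = c(0.1, 0.9),
                        apathy_base = 30, apathy_group_effect = 6,
                        apathy_loading = -4, apathy_noise_sd = 8,
                        seed = 1L) {
  for (g in names(groups)) {
    if (is.null(groups[[g]]$n) || groups[[g]]$n < 1) {
      stop("group '", g, "' needs a subject count n >= 1")
    }
    if (is.null(groups[[g]]$model_id)) groups[[g]]$model_id <- "vkf"
    if (is.null(groups[[g]]$dist)) groups[[g]]$dist <- agent_param_dist()
  }
  if (apathy_noise_sd < 0) stop("noise scales must be >= 0")
  structure(
    list(groups = groups, n_trials = n_trials, n_arms = n_arms,
         step_prob = step_prob, step_size = step_size, bounds = bounds,
         apathy_base = apathy_base, apathy_group_effect = apathy_group_effect,
         apathy_loading = apathy_loading, apathy_noise_sd = apathy_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default two-group design: adaptive controls vs impaired-adaptation group
#'
#' 39 control-like (`HC`) and 26 patient-like (`TMD`) binary-VKF agents.
#' Control-like agents start with initial uncertainty/volatility well
#' above its operating level, so their trial-wise uncertainty and
#' learning rate visibly decay with experience (adaptive trajectories).
#' Patient-like agents draw higher volatility learning rates with initial
#' volatility at the operating level, yielding flat or growing
#' trajectories — the failure-to-reduce-uncertainty phenotype.
#'
#' @param n_hc,n_tmd group sizes.
#' @return named list usable as the `groups` argument of [cohort_spec()].
#' @export
default_groups <- function(n_hc = 39, n_tmd = 26) {
  common <- list(sigma2 = c(log(0.8), 0.3), beta_v = c(log(5), 0.25),
                 beta_u = c(log(0.5), 0.3))
  list(
    HC = list(n = n_hc, model_id = "vkf",
              dist = do.call(agent_param_dist,
                             c(list(lambda = c(stats::qlogis(0.05), 0.4),
                                    v0 = c(log(8), 0.3)), common))),
    TMD = list(n = n_tmd, model_id = "vkf",
               dist = do.call(agent_param_dist,
                              c(list(lambda = c(stats::qlogis(0.3), 0.4),
                                     v0 = c(log(0.5), 0.3)), common)))
  )
}

#' Simulate a full synthetic cohort
#'
#' Generates one fresh schedule and agent per subject according to the
#' cohort specification, computes each agent's true uncertainty-adaptation
#' index from its own latent trajectory, and generates questionnaire
#' scores with the specified group effect and mediation structure.
#'
#' @param spec a [cohort_spec()].
#' @return a list of `subject_dataset`s with class `cohort`; the true
#'   generating parameters and adaptation indices are in
#'   `attr(, "truth")`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- withr::with_seed(spec$seed,
    sample.int(.Machine$integer.max, sum(vapply(spec$groups, `[[`, 0, "n")) + 1L))
  subjects <- list()
  truth <- list()
  idx <- 0L
  for (g in names(spec$groups)) {
    grp <- spec$groups[[g]]
    for (i in seq_len(grp$n)) {
      idx <- idx + 1L
      sid <- sprintf("%s%03d", g, i)
      s_seed <- seeds[idx]
      sch <- generate_reward_schedule(spec$n_trials, spec$n_arms,
                                      spec$step_prob, spec$step_size,
                                      spec$bounds, seed = s_seed)
      pars <- withr::with_seed(s_seed + 1L,
                               draw_agent_params(grp$model_id, grp$dist))
      ds <- simulate_agent(sch, grp$model_id, pars, seed = s_seed + 2L,
                           subject_id = sid, group = g)
      lat <- attr(ds, "latent")
      unc <- latent_series(lat, "uncertainty")
      idx_val <- adaptation_index(unc)$index
      truth[[sid]] <- data.frame(subject_id = sid, group = g,
                                 t(pars), true_index = idx_val)
      subjects[[sid]] <- ds
    }
  }
  truth <- do.call(rbind, truth)
  # questionnaire scores: linear structural model on the true index
  z_index <- as.numeric(scale(truth$true_index))
  if (any(!is.finite(z_index))) z_index[!is.finite(z_index)] <- 0
  is_g2 <- as.numeric(truth$group == names(spec$groups)[2])
  score_seed <- seeds[length(seeds)]
  scores <- withr::with_seed(score_seed, {
    n <- nrow(truth)
    ami <- spec$apathy_base + spec$apathy_group_effect * is_g2 +
      spec$apathy_loading * z_index + stats::rnorm(n, 0, spec$apathy_noise_sd)
    data.frame(
      subject_id = truth$subject_id,
      vas = pmin(pmax(round(stats::rnorm(n, 6 + 30 * is_g2, 10 + 10 * is_g2)), 0), 100),
      ami = round(ami, 1),
      phq9 = pmin(pmax(round(stats::rnorm(n, 3 + 7 * is_g2, 2.5 + 1.5 * is_g2)), 0), 27),
      pcs = pmin(pmax(round(stats::rnorm(n, 8 + 12 * is_g2, 6 + 3 * is_g2)), 0), 52),
      eq5d = pmin(pmax(round(stats::rnorm(n, 0.92 - 0.14 * is_g2, 0.08 + 0.04 * is_g2), 3), 0), 1),
      gcps = ifelse(is_g2 == 1,
                    sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                           prob = c(0.42, 0.27, 0.23, 0.08)),
                    sample(c("I", "II"), n, replace = TRUE, prob = c(0.9, 0.1))))
  })
  for (i in seq_along(subjects)) {
    sc <- scores[scores$subject_id == subjects[[i]]$subject_id, -1]
    subjects[[i]]$scores <- as.list(sc)
  }
  structure(subjects, class = "cohort", truth = truth, spec = spec)
}

#' @export
print.cohort <- function(x, ...) {
  grp <- table(vapply(x, `[[`, "", "group"))
  cat(sprintf("<cohort> %d subjects (%s)\n", length(x),
              paste(names(grp), grp, sep = "=", collapse = ", ")))
  invisible(x)
}
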