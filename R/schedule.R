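#' Generate a restless-bandit reward schedule
#'
#' Builds the hidden reward-probability environment of a restless multi-armed
#' bandit: each arm's reward probability follows an independent bounded
#' step random walk. On every trial each arm has probability `step_prob` of
#' proposing a step of `+step_size` or `-step_size` (equally likely); a
#' proposed step that would leave `bounds` is rejected and the value held,
#' so probabilities stay on the grid defined by the starting value and
#' `step_size`.
#'
#' @param n_trials number of trials (>= 1).
#' @param n_arms number of arms (>= 2).
#' @param step_prob per-trial, per-arm probability of a change proposal.
#' @param step_size magnitude of a single probability step.
#' @param bounds length-2 numeric, lower and upper probability bounds in
#'   `[0, 1]`.
#' @param seed integer seed; the same arguments and seed reproduce the
#'   schedule exactly.
#'
#' @return An object of class `reward_schedule`: a list with `probs`
#'   (`n_trials x n_arms` matrix of reward probabilities), `step_size`,
#'   `step_prob`, `bounds` and `seed`.
#'
#' @examples
#' sch <- generate_reward_schedule(200, 3, seed = 1)
#' range(sch$probs)
#' @export
generate_reward_schedule <- function(n_trials, n_arms = 3, step_prob = 0.1,
                                     step_size = 0.1, bounds = c(0.1, 0.9),
                                     seed = 1L) {
  if (length(n_trials) != 1L || n_trials < 1) stop("n_trials must be >= 1")
  if (length(n_arms) != 1L || n_arms < 2) stop("n_arms must be >= 2")
  if (step_prob < 0 || step_prob > 1) stop("step_prob must be in [0, 1]")
  if (step_size < 0) stop("step_size must be non-negative")
  if (length(bounds) != 2L || bounds[1] >= bounds[2] ||
      bounds[1] < 0 || bounds[2] > 1) {
    stop("bounds must be an ordered pair within [0, 1]")
  }
  n_trials <- as.integer(n_trials)
  n_arms <- as.integer(n_arms)

  probs <- withr::with_seed(seed, {
    # start each arm uniformly on the step grid inside the bounds
    grid <- seq(bounds[1], bounds[2], by = if (step_size > 0) step_size else
      (bounds[2] - bounds[1]))
    p <- matrix(NA_real_, n_trials, n_arms)
    p[1, ] <- grid[sample.int(length(grid), n_arms, replace = TRUE)]
    if (n_trials > 1) {
      for (t in 2:n_trials) {
        cur <- p[t - 1, ]
        move <- stats::runif(n_arms) < step_prob
        dir <- sample(c(-1, 1), n_arms, replace = TRUE)
        prop <- cur + ifelse(move, dir * step_size, 0)
        # reject (hold) proposals that would exit the bounds
        bad <- prop < bounds[1] - 1e-12 | prop > bounds[2] + 1e-12
        prop[bad] <- cur[bad]
        p[t, ] <- prop
      }
    }
    p
  })
  colnames(probs) <- paste0("arm", seq_len(n_arms))
  structure(
    list(probs = probs, step_size = step_size, step_prob = step_prob,
         bounds = bounds, seed = as.integer(seed)),
    class = "reward_schedule"
  )
}

#' @export
print.reward_schedule <- function(x, ...) {
  cat(sprintf(
    "<reward_schedule> %d trials x %d arms, step %.3g w.p. %.3g, bounds [%g, %g], seed %d\n",
    nrow(x$probs), ncol(x$probs), x$step_size, x$step_prob,
    x$bounds[1], x$bounds[2], x$seed))
  invisible(x)
}

n_trials_of <- function(schedule) nrow(schedule$probs)
n_arms_of <- function(schedule) ncol(schedule$probs)
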