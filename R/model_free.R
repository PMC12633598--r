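# ---- model-free behavioural metrics -----------------------------------------

# consecutive-trial pairs where both trials are valid; invalid trials break
# the chain. Returns indices t such that (t, t+1) is eligible.
eligible_pairs <- function(trials) {
  v <- trials$valid & !is.na(trials$choice)
  n <- nrow(trials)
  if (n < 2) return(integer(0))
  which(v[-n] & v[-1] & diff(trials$trial) == 1)
}

#' Win-stay rate
#'
#' Fraction of rewarded valid trials whose immediately following valid
#' trial repeats the same choice.
#'
#' @param dataset a `subject_dataset`.
#' @return rate in `[0, 1]`, or `NA` (with a warning) when no rewarded
#'   trial has a valid successor.
#' @export
win_stay <- function(dataset) {
  tr <- dataset$trials
  t1 <- eligible_pairs(tr)
  t1 <- t1[tr$outcome[t1] %in% 1]
  if (!length(t1)) {
    warning("no eligible rewarded trials; win_stay is NA")
    return(NA_real_)
  }
  mean(tr$choice[t1 + 1] == tr$choice[t1])
}

#' Lose-shift rate
#'
#' Fraction of non-rewarded valid trials whose immediately following valid
#' trial switches to a different choice.
#'
#' @inheritParams win_stay
#' @return rate in `[0, 1]`, or `NA` (with a warning) when undefined.
#' @export
lose_shift <- function(dataset) {
  tr <- dataset$trials
  t1 <- eligible_pairs(tr)
  t1 <- t1[tr$outcome[t1] %in% 0]
  if (!length(t1)) {
    warning("no eligible non-rewarded trials; lose_shift is NA")
    return(NA_real_)
  }
  mean(tr$choice[t1 + 1] != tr$choice[t1])
}

#' Lag-1 autocorrelation of the choice sequence
#'
#' Autocorrelation of the valid choice sequence with choices encoded as
#' their numeric arm indices:
#' `r = sum (c_t - mean)(c_{t+1} - mean) / sum (c_t - mean)^2`.
#' The encoding makes this metric label-dependent; it indexes choice
#' perseveration, not reward sensitivity.
#'
#' @inheritParams win_stay
#' @return coefficient in `[-1, 1]`, or `NA` (with a warning) for a
#'   constant sequence or fewer than 3 valid trials.
#' @export
lag1_autocorrelation <- function(dataset) {
  x <- dataset$trials$choice[dataset$trials$valid]
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3 || stats::var(x) == 0) {
    warning("constant or too-short choice sequence; lag-1 autocorrelation is NA")
    return(NA_real_)
  }
  xb <- mean(x)
  sum((x[-n] - xb) * (x[-1] - xb)) / sum((x - xb)^2)
}

#' Best-option tracking rate
#'
#' Fraction of valid trials on which the chosen arm had the maximal
#' scheduled reward probability. Ties split credit equally: choosing any
#' of `k` tied-best arms earns `1/k`.
#'
#' @inheritParams win_stay
#' @return rate in `[0, 1]`.
#' @export
best_option_rate <- function(dataset) {
  if (is.null(dataset$schedule)) stop("best_option_rate requires a schedule")
  tr <- dataset$trials
  probs <- dataset$schedule$probs
  keep <- which(tr$valid & !is.na(tr$choice))
  credit <- vapply(keep, function(i) {
    row <- probs[tr$trial[i], ]
    best <- which(row >= max(row) - 1e-12)
    if (tr$choice[i] %in% best) 1 / length(best) else 0
  }, numeric(1))
  mean(credit)
}

#' Reward sensitivity: choice frequency vs arm reward rate
#'
#' Pearson correlation, across arms, between the subject's choice
#' frequency for each arm (over valid trials) and the arm's average
#' scheduled reward probability.
#'
#' @inheritParams win_stay
#' @return correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   vector is degenerate.
#' @export
reward_sensitivity <- function(dataset) {
  if (is.null(dataset$schedule)) stop("reward_sensitivity requires a schedule")
  tr <- dataset$trials
  ch <- tr$choice[tr$valid & !is.na(tr$choice)]
  freq <- tabulate(ch, dataset$n_arms) / length(ch)
  rate <- colMeans(dataset$schedule$probs)
  if (stats::sd(freq) == 0 || stats::sd(rate) == 0) {
    warning("degenerate choice frequencies or arm rates; reward_sensitivity is NA")
    return(NA_real_)
  }
  stats::cor(freq, rate)
}

#' Individualized chance level and above-chance binomial test
#'
#' The subject's personal chance level is the grand mean of the scheduled
#' reward probabilities over all trials and arms (what uniform random
#' choosing would earn on this bandit instantiation). The observed reward
#' count over valid trials is tested against `Binomial(n_valid, chance)`
#' with an exact one-sided (above-chance) tail probability.
#'
#' @inheritParams win_stay
#' @return list with `chance`, `reward_count`, `n_valid`, `p_value`.
#' @export
chance_level_test <- function(dataset) {
  if (is.null(dataset$schedule)) stop("chance_level_test requires a schedule")
  tr <- dataset$trials
  chance <- mean(dataset$schedule$probs)
  k <- sum(tr$outcome[tr$valid], na.rm = TRUE)
  n <- sum(tr$valid)
  p <- stats::pbinom(k - 1, n, chance, lower.tail = FALSE)
  list(chance = chance, reward_count = k, n_valid = n, p_value = p)
}

#' Binned temporal dynamics of win-stay and lose-shift
#'
#' Splits the trial sequence into consecutive fixed-width bins
#' (`floor(n_trials / bin_width)` bins; 20 bins for 200 trials at the
#' default width of 10), scores win-stay and lose-shift within each bin,
#' and aggregates the early (trials 1-50), middle (51-100) and late
#' (151-200) learning phases.
#'
#' @inheritParams win_stay
#' @param bin_width trials per bin.
#' @param phases named list of `c(first, last)` trial windows.
#' @return list with `bins` (data frame: `bin`, `first`, `last`,
#'   `win_stay`, `lose_shift`) and `phases` (data frame per phase).
#' @export
binned_dynamics <- function(dataset, bin_width = 10,
                            phases = list(early = c(1, 50),
                                          middle = c(51, 100),
                                          late = c(151, 200))) {
  tr <- dataset$trials
  n <- max(tr$trial)
  if (n < bin_width) stop("need at least one full bin of trials")
  n_bins <- floor(n / bin_width)
  score_window <- function(first, last) {
    sub <- tr[tr$trial >= first & tr$trial <= last, , drop = FALSE]
    ds <- dataset
    ds$trials <- sub
    c(win_stay = suppressWarnings(win_stay(ds)),
      lose_shift = suppressWarnings(lose_shift(ds)))
  }
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    first <- (b - 1) * bin_width + 1
    last <- b * bin_width
    data.frame(bin = b, first = first, last = last,
               t(score_window(first, last)))
  }))
  ph <- do.call(rbind, lapply(names(phases), function(p) {
    w <- phases[[p]]
    data.frame(phase = p, first = w[1], last = w[2], t(score_window(w[1], w[2])))
  }))
  list(bins = bins, phases = ph)
}

#' Model-free metric report for one subject
#'
#' Computes the full battery of model-agnostic behavioural metrics:
#' win-stay, lose-shift, lag-1 choice autocorrelation, best-option
#' tracking, reward sensitivity, and the individualized chance-level test.
#'
#' @inheritParams win_stay
#' @return one-row data frame.
#' @export
compute_metrics <- function(dataset) {
  clt <- if (!is.null(dataset$schedule)) chance_level_test(dataset) else
    list(chance = NA_real_, reward_count = sum(dataset$trials$outcome,
                                               na.rm = TRUE),
         n_valid = n_valid_trials(dataset), p_value = NA_real_)
  data.frame(
    subject_id = dataset$subject_id,
    group = dataset$group,
    n_valid = n_valid_trials(dataset),
    win_stay = suppressWarnings(win_stay(dataset)),
    lose_shift = suppressWarnings(lose_shift(dataset)),
    lag1_autocorr = suppressWarnings(lag1_autocorrelation(dataset)),
    best_option_rate = if (!is.null(dataset$schedule))
      best_option_rate(dataset) else NA_real_,
    reward_sensitivity_r = if (!is.null(dataset$schedule))
      suppressWarnings(reward_sensitivity(dataset)) else NA_real_,
    chance_level = clt$chance,
    reward_count = clt$reward_count,
    above_chance_p = clt$p_value,
    mean_rt = mean(dataset$trials$rt[dataset$trials$valid], na.rm = TRUE))
}

#' Model-free metrics for every subject in a cohort
#'
#' @param cohort list of `subject_dataset`s.
#' @return data frame, one row per subject (see [compute_metrics()]).
#' @export
cohort_metrics <- function(cohort) {
  do.call(rbind, lapply(cohort, compute_metrics))
}
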