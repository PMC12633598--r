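#' @useDynLib vkfbandit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- model registry ---------------------------------------------------------

# model_id -> free parameters, their constraints, and the softmax inputs.
# Constraints: "unit" (sigmoid transform) or "pos" (exp transform).
MODEL_REGISTRY <- list(
  rw1 = list(
    params = c(alpha = "unit", beta_v = "pos"),
    variant = "V", inputs = "raw", code = 1L),
  rw2 = list(
    params = c(alpha_pos = "unit", alpha_neg = "unit", beta_v = "pos"),
    variant = "V", inputs = "raw", code = 2L),
  kf = list(
    params = c(v = "pos", sigma2 = "pos", beta_v = "pos"),
    variant = "V", inputs = "relative", code = 3L),
  vkf = list(
    params = c(lambda = "unit", v0 = "pos", sigma2 = "pos",
               beta_v = "pos", beta_u = "pos"),
    variant = "V+U", inputs = "relative", code = 4L),
  vkf_rv = list(
    params = c(lambda = "unit", v0 = "pos", sigma2 = "pos", beta_v = "pos"),
    variant = "V", inputs = "relative", code = 5L)
)

#' List the learning models known to the package
#'
#' @return Character vector of model identifiers: `rw1` and `rw2`
#'   (Rescorla-Wagner with one or two learning rates), `kf` (constant-noise
#'   Kalman filter), `vkf` (binary volatile Kalman filter, softmax over
#'   relative value and relative uncertainty) and `vkf_rv` (volatile Kalman
#'   filter with relative value only).
#' @export
model_ids <- function() names(MODEL_REGISTRY)

model_info <- function(model_id) {
  info <- MODEL_REGISTRY[[model_id]]
  if (is.null(info)) stop("unknown model_id: ", model_id)
  info
}

#' Names of a model's free parameters
#' @param model_id model identifier, see [model_ids()].
#' @return character vector of parameter names.
#' @export
model_param_names <- function(model_id) names(model_info(model_id)$params)

# validate a named parameter vector/list for a model; returns named numeric
validate_params <- function(model_id, params) {
  info <- model_info(model_id)
  need <- names(info$params)
  params <- unlist(params)
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("missing parameters for model '", model_id, "': ",
         paste(missing, collapse = ", "))
  }
  p <- params[need]
  unit <- need[info$params == "unit"]
  pos <- need[info$params == "pos"]
  if (any(p[unit] < 0 | p[unit] > 1)) {
    stop("unit-range parameters must lie in [0, 1]: ",
         paste(unit[p[unit] < 0 | p[unit] > 1], collapse = ", "))
  }
  # decision weights may be exactly 0 (uniform-policy limit); variance-like
  # parameters must be strictly positive
  strict <- setdiff(pos, c("beta_v", "beta_u"))
  if (any(p[strict] <= 0)) {
    stop("variance parameters must be positive: ",
         paste(strict[p[strict] <= 0], collapse = ", "))
  }
  if (any(p[pos] < 0)) {
    stop("decision weights must be non-negative: ",
         paste(pos[p[pos] < 0], collapse = ", "))
  }
  p
}

# ---- single-step updates ----------------------------------------------------

#' Rescorla-Wagner value update
#'
#' Delta-rule update of the chosen arm's value,
#' `v' = v + alpha * (R - v)`. The two-learning-rate variant (`rw2`)
#' applies `alpha_pos` after reward (`R = 1`) and `alpha_neg` after
#' non-reward (`R = 0`). Unchosen arms are untouched.
#'
#' @param state list with element `m`, the per-arm value vector.
#' @param choice chosen arm index (1-based).
#' @param outcome observed reward, 0 or 1.
#' @param params named parameters (`alpha`, or `alpha_pos`/`alpha_neg`).
#' @param model_id `"rw1"` or `"rw2"`.
#' @return the updated state list.
#' @export
rw_update <- function(state, choice, outcome, params, model_id = "rw1") {
  if (!outcome %in% c(0, 1)) stop("outcome must be 0 or 1")
  params <- unlist(params)
  alpha <- if (model_id == "rw2") {
    if (outcome == 1) params[["alpha_pos"]] else params[["alpha_neg"]]
  } else {
    params[["alpha"]]
  }
  if (alpha < 0 || alpha > 1) stop("learning rate must be in [0, 1]")
  state$m[choice] <- state$m[choice] + alpha * (outcome - state$m[choice])
  state
}

#' Kalman filter update for one bandit trial
#'
#' Standard predict-then-update Kalman step on the chosen arm with constant
#' process-noise variance `v` and observation-noise variance `sigma2`:
#' gain `k = (w + v) / (w + v + sigma2)`, mean `m' = m + k (O - m)`,
#' posterior variance `w' = (1 - k)(w + v)`. Unchosen arms keep their mean
#' but diffuse, `w <- w + v`, reflecting continued drift of the hidden
#' reward probabilities while unobserved.
#'
#' @param state list with per-arm `m` (means) and `w` (posterior variances).
#' @param choice chosen arm index (1-based).
#' @param outcome observed reward, 0 or 1.
#' @param params named parameters with `v` and `sigma2` (both positive).
#' @return updated state, with `k` set to the chosen arm's gain.
#' @export
kf_update <- function(state, choice, outcome, params) {
  params <- unlist(params)
  v <- params[["v"]]; sigma2 <- params[["sigma2"]]
  if (v <= 0 || sigma2 <= 0) stop("v and sigma2 must be positive")
  w <- state$w; m <- state$m
  k <- (w[choice] + v) / (w[choice] + v + sigma2)
  m[choice] <- m[choice] + k * (outcome - m[choice])
  wc <- max((1 - k) * (w[choice] + v), 1e-12)
  w <- w + v           # unobserved arms keep diffusing
  w[choice] <- wc
  state$m <- m; state$w <- w; state$k <- k
  state
}

#' Volatile Kalman filter update for one binary bandit trial
#'
#' Binary VKF step on the chosen arm. The process-noise variance
#' (volatility) `v` is itself learned: with gain
#' `k = (w + v) / (w + v + sigma2)` the mean and variance update as in the
#' Kalman filter, the lag-one autocovariance is `w_cov = (1 - k) w`, and
#' the volatility moves at rate `lambda` towards the realized squared belief
#' change, `v' = v + lambda * ((m' - m)^2 + w + w' - 2 w_cov - v)`.
#' Volatility is tracked per arm and only the chosen arm's `v` updates;
#' unchosen arms diffuse (`w <- w + v`) by their own current volatility.
#'
#' @param state list with per-arm `m`, `w` and `v`.
#' @param choice chosen arm index (1-based).
#' @param outcome observed reward, 0 or 1.
#' @param params named parameters with `lambda` (in `[0, 1]`) and `sigma2`
#'   (positive).
#' @return updated state, with `k` set to the chosen arm's gain.
#' @export
vkf_update <- function(state, choice, outcome, params) {
  params <- unlist(params)
  lambda <- params[["lambda"]]; sigma2 <- params[["sigma2"]]
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (any(state$w <= 0) || any(state$v <= 0)) stop("w and v must be positive")
  m <- state$m; w <- state$w; v <- state$v
  i <- choice
  k <- (w[i] + v[i]) / (w[i] + v[i] + sigma2)
  m_new <- m[i] + k * (outcome - m[i])
  w_new <- max((1 - k) * (w[i] + v[i]), 1e-12)
  w_cov <- (1 - k) * w[i]
  # floor guards against multiplicative underflow at extreme parameters
  v_new <- max(v[i] + lambda *
                 ((m_new - m[i])^2 + w[i] + w_new - 2 * w_cov - v[i]), 1e-12)
  w <- w + v           # unobserved arms keep diffusing (per-arm volatility)
  m[i] <- m_new
  w[i] <- w_new
  v[i] <- v_new
  state$m <- m; state$w <- w; state$v <- v; state$k <- k
  state
}

# ---- choice rules -----------------------------------------------------------

#' Softmax choice probabilities over values and uncertainties
#'
#' Computes per-arm choice probabilities
#' `P_i = exp(beta_v * V_i + beta_u * U_i) / sum_j exp(...)` with
#' overflow-safe normalization. The `variant` selects which terms enter the
#' exponent: `"V"` uses values only, `"U"` uncertainties only, `"V+U"` both.
#'
#' @param values per-arm value inputs.
#' @param uncertainties per-arm uncertainty inputs (same length).
#' @param beta_v,beta_u decision weights.
#' @param variant one of `"V"`, `"U"`, `"V+U"`.
#' @return numeric vector of probabilities summing to 1.
#' @examples
#' softmax_policy(c(1, 0, 0), c(0, 0, 0), beta_v = 1, beta_u = 0)
#' @export
softmax_policy <- function(values, uncertainties = rep(0, length(values)),
                           beta_v = 1, beta_u = 0,
                           variant = c("V+U", "V", "U")) {
  variant <- match.arg(variant)
  if (length(values) != length(uncertainties)) {
    stop("values and uncertainties must have equal length")
  }
  z <- switch(variant,
    "V" = beta_v * values,
    "U" = beta_u * uncertainties,
    "V+U" = beta_v * values + beta_u * uncertainties)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Relative (share-of-total) transform
#'
#' Divides each arm's quantity by the sum over arms, giving the chosen
#' option's relative value `RV = m_chosen / sum(m)` or relative uncertainty
#' `RU = w_chosen / sum(w)` when indexed at the chosen arm.
#'
#' @param x per-arm positive quantities.
#' @return vector of the same length summing to 1.
#' @export
relative_transform <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("relative_transform requires positive finite inputs")
  }
  x / sum(x)
}

# ---- sequential filtering ---------------------------------------------------

init_state <- function(model_id, params, n_arms, m0 = 0.5, w0 = NULL) {
  params <- unlist(params)
  switch(model_id,
    rw1 = ,
    rw2 = list(m = rep(m0, n_arms)),
    kf = {
      if (is.null(w0)) w0 <- params[["v"]]
      list(m = rep(m0, n_arms), w = rep(w0, n_arms))
    },
    vkf = ,
    vkf_rv = {
      if (is.null(w0)) w0 <- params[["v0"]]
      list(m = rep(m0, n_arms), w = rep(w0, n_arms),
           v = rep(params[["v0"]], n_arms))
    },
    stop("unknown model_id: ", model_id))
}

policy_of_state <- function(state, model_id, params, info = model_info(model_id)) {
  params <- unlist(params)
  beta_v <- if ("beta_v" %in% names(params)) params[["beta_v"]] else 0
  beta_u <- if ("beta_u" %in% names(params)) params[["beta_u"]] else 0
  if (info$inputs == "raw") {
    vals <- state$m
    unc <- rep(0, length(vals))
  } else {
    # floor guards against means underflowing to 0 under extreme gains
    vals <- relative_transform(pmax(state$m, 1e-12))
    unc <- if (!is.null(state$w)) relative_transform(pmax(state$w, 1e-12)) else
      rep(0, length(vals))
  }
  list(p = softmax_policy(vals, unc, beta_v, beta_u, variant = info$variant),
       rv = vals, ru = unc)
}

step_state <- function(state, model_id, choice, outcome, params) {
  switch(model_id,
    rw1 = rw_update(state, choice, outcome, params, "rw1"),
    rw2 = rw_update(state, choice, outcome, params, "rw2"),
    kf = kf_update(state, choice, outcome, params),
    vkf = ,
    vkf_rv = vkf_update(state, choice, outcome, params))
}

#' Filter a subject's choices through a learning model
#'
#' Runs the specified model sequentially over a subject's observed choices
#' and outcomes, returning the full latent trajectory and the log
#' probability the model's softmax policy assigned to each realized choice.
#' The policy at each trial uses the pre-choice (prior) latent quantities;
#' invalid trials are skipped without any state update.
#'
#' @param dataset a `subject_dataset`, see [simulate_agent()] or
#'   [load_cohort()].
#' @param model_id model identifier, see [model_ids()].
#' @param params named parameter vector for the model.
#' @param m0 initial mean (default 0.5, the probability midpoint).
#' @param w0 initial posterior variance; defaults to the model's
#'   process-noise / initial-volatility parameter.
#' @return a `latent_trajectory`: data frame with one row per valid trial
#'   (`trial`, `choice`, `outcome`, `k`, `rv`, `ru`, `logp`, and per-arm
#'   `m.armJ`, `w.armJ`, `v.armJ` columns where defined), with the total
#'   log-likelihood in `attr(, "loglik")`.
#' @export
run_model <- function(dataset, model_id, params, m0 = 0.5, w0 = NULL) {
  info <- model_info(model_id)
  params <- validate_params(model_id, params)
  tr <- dataset$trials
  n_arms <- dataset$n_arms
  state <- init_state(model_id, params, n_arms, m0 = m0, w0 = w0)
  keep <- which(tr$valid & !is.na(tr$choice))
  n <- length(keep)
  arm_nm <- paste0("arm", seq_len(n_arms))
  out <- list(
    trial = tr$trial[keep], choice = tr$choice[keep], outcome = tr$outcome[keep],
    m = matrix(NA_real_, n, n_arms, dimnames = list(NULL, arm_nm)),
    w = matrix(NA_real_, n, n_arms, dimnames = list(NULL, arm_nm)),
    v = matrix(NA_real_, n, n_arms, dimnames = list(NULL, arm_nm)),
    k = rep(NA_real_, n), rv = rep(NA_real_, n), ru = rep(NA_real_, n),
    logp = rep(NA_real_, n))
  for (j in seq_len(n)) {
    i <- keep[j]
    ch <- tr$choice[i]
    if (ch < 1 || ch > n_arms) stop("choice index out of range at trial ", tr$trial[i])
    pol <- policy_of_state(state, model_id, params, info)
    out$logp[j] <- log(pol$p[ch])
    out$rv[j] <- pol$rv[ch]
    out$ru[j] <- pol$ru[ch]
    state <- step_state(state, model_id, ch, tr$outcome[i], params)
    out$m[j, ] <- state$m
    if (!is.null(state$w)) out$w[j, ] <- state$w
    if (!is.null(state$v)) out$v[j, ] <- state$v
    if (!is.null(state$k)) out$k[j] <- state$k
  }
  df <- data.frame(trial = out$trial, choice = out$choice, outcome = out$outcome,
                   k = out$k, rv = out$rv, ru = out$ru, logp = out$logp)
  df <- cbind(df, as.data.frame(out$m) |> stats::setNames(paste0("m.", arm_nm)))
  if (!is.null(state$w)) {
    df <- cbind(df, as.data.frame(out$w) |> stats::setNames(paste0("w.", arm_nm)))
  }
  if (!is.null(state$v)) {
    df <- cbind(df, as.data.frame(out$v) |> stats::setNames(paste0("v.", arm_nm)))
  }
  attr(df, "loglik") <- sum(out$logp)
  attr(df, "model_id") <- model_id
  attr(df, "params") <- params
  class(df) <- c("latent_trajectory", "data.frame")
  df
}

#' Negative log-likelihood of a subject's choices under a model
#'
#' Fast objective for fitting: `-sum_t log p(choice_t)` over valid trials,
#' computed in compiled code. Agrees with the sum of `logp` from
#' [run_model()] to numerical precision.
#'
#' @inheritParams run_model
#' @return a non-negative scalar; 0 (with a warning) for a dataset without
#'   valid trials.
#' @export
negative_log_likelihood <- function(dataset, model_id, params, m0 = 0.5,
                                    w0 = NULL) {
  info <- model_info(model_id)
  params <- validate_params(model_id, params)
  tr <- dataset$trials
  keep <- tr$valid & !is.na(tr$choice)
  if (!any(keep)) {
    warning("dataset has no valid trials; NLL is 0")
    return(0)
  }
  ch <- as.integer(tr$choice[keep])
  oc <- as.numeric(tr$outcome[keep])
  if (any(ch < 1 | ch > dataset$n_arms)) stop("choice index out of range")
  nll_cpp(ch, oc, info$code, params[names(info$params)],
          as.integer(dataset$n_arms), m0,
          if (is.null(w0)) -1.0 else w0)
}
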