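# ---- latent-trajectory characterization -------------------------------------

#' Extract a named latent series from a model trajectory
#'
#' Pulls the trial-wise series used in adaptation analyses from a
#' [run_model()] / [simulate_agent()] latent trajectory: `volatility`
#' (chosen-arm v), `uncertainty` (chosen-arm posterior variance w) or
#' `learning_rate` (Kalman gain k of the chosen arm). `arm = "mean"`
#' averages over arms instead of following the chosen arm.
#'
#' @param trajectory a `latent_trajectory` data frame.
#' @param series one of `"volatility"`, `"uncertainty"`, `"learning_rate"`.
#' @param arm `"chosen"` (default) or `"mean"`.
#' @return numeric vector, one value per valid trial, with the trial
#'   indices in `attr(, "trial")`.
#' @export
latent_series <- function(trajectory,
                          series = c("volatility", "uncertainty", "learning_rate"),
                          arm = c("chosen", "mean")) {
  series <- match.arg(series)
  arm <- match.arg(arm)
  prefix <- switch(series, volatility = "v.", uncertainty = "w.",
                   learning_rate = NULL)
  if (series == "learning_rate") {
    out <- trajectory$k
  } else {
    cols <- grep(paste0("^", sub(".", "\\.", prefix, fixed = TRUE)),
                 names(trajectory), value = TRUE)
    if (!length(cols)) stop("trajectory has no ", series, " columns")
    mat <- as.matrix(trajectory[, cols, drop = FALSE])
    out <- if (arm == "chosen") {
      mat[cbind(seq_len(nrow(mat)), trajectory$choice)]
    } else {
      rowMeans(mat)
    }
  }
  attr(out, "trial") <- trajectory$trial
  out
}

#' Ordinary least-squares slope of a trial-indexed series
#'
#' @param series numeric values; trial indices taken from
#'   `attr(series, "trial")` or `x`.
#' @param x optional trial numbers.
#' @return list with `slope`, `intercept`, `p_value` (two-sided test of
#'   zero slope), `se`.
#' @export
linear_slope <- function(series, x = NULL) {
  y <- as.numeric(series)
  if (is.null(x)) x <- attr(series, "trial")
  if (is.null(x)) x <- seq_along(y)
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3) stop("linear_slope needs at least 3 points")
  fit <- stats::lm(y ~ x)
  # summary() warns on exact fits; the zero-SE case is handled below
  sm <- suppressWarnings(summary(fit)$coefficients)
  p <- if (nrow(sm) < 2 || is.na(sm[2, 2]) || sm[2, 2] == 0) {
    if (abs(stats::coef(fit)[2]) < 1e-12) 1 else 0
  } else sm[2, 4]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = unname(p),
       se = if (nrow(sm) >= 2) unname(sm[2, 2]) else NA_real_)
}

#' Exponential fit of a latent trajectory
#'
#' Fits `f(x) = a * exp(b * x)` over trial numbers by nonlinear least
#' squares with multiple starts spanning both signs of `b` (plus a
#' log-linear initialization for positive data). The time constant
#' `tau = -1/b` is defined for decaying fits (`b < 0`) and gives the
#' number of trials for the series to fall to `1/e` (about 37%) of its
#' initial value.
#'
#' @inheritParams linear_slope
#' @return list with `a`, `b`, `tau` (`NA` unless `b < 0`), `p_value`
#'   (two-sided test of `b = 0`), `r_squared`, `converged`.
#' @export
exponential_fit <- function(series, x = NULL) {
  y <- as.numeric(series)
  if (is.null(x)) x <- attr(series, "trial")
  if (is.null(x)) x <- seq_along(y)
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 4) stop("exponential_fit needs at least 4 points")

  starts <- list(c(a = max(abs(y[1]), 1e-6), b = -0.01),
                 c(a = max(abs(y[1]), 1e-6), b = 0.01),
                 c(a = mean(y), b = -0.001),
                 c(a = mean(y), b = 0.001))
  if (all(y > 0)) {
    ll <- stats::lm(log(y) ~ x)
    starts <- c(list(c(a = exp(stats::coef(ll)[1]),
                       b = unname(stats::coef(ll)[2]))), starts)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x), start = as.list(s),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(a = NA_real_, b = NA_real_, tau = NA_real_,
                p_value = NA_real_, r_squared = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(best$fit)
  sm <- summary(best$fit)$coefficients
  tss <- sum((y - mean(y))^2)
  p_b <- if ("b" %in% rownames(sm) && is.finite(sm["b", 2]) && sm["b", 2] > 0)
    2 * stats::pt(-abs(sm["b", 1] / sm["b", 2]), length(y) - 2) else NA_real_
  list(a = unname(cf["a"]), b = unname(cf["b"]),
       tau = if (is.finite(cf["b"]) && cf["b"] < 0) -1 / unname(cf["b"]) else NA_real_,
       p_value = p_b,
       r_squared = if (tss > 0) 1 - best$rss / tss else NA_real_,
       converged = TRUE)
}

#' Classify a trajectory from its exponential rate
#'
#' Rule table: `b < 0` is exponential decay (adaptive learning), `b > 0`
#' exponential growth (maladaptive trajectory), `b = 0` flat. With
#' `require_significance = TRUE` a non-significant `b` (at `alpha`) is
#' classified flat regardless of sign.
#'
#' @param b fitted exponential rate.
#' @param p_value two-sided p-value of `b = 0` (used only when
#'   significance is required).
#' @param require_significance demand `p < alpha` for a non-flat class.
#' @param alpha significance threshold.
#' @return one of `"decay"`, `"flat"`, `"growth"`.
#' @export
classify_trajectory <- function(b, p_value = NA_real_,
                                require_significance = FALSE, alpha = 0.05) {
  if (is.na(b)) return(NA_character_)
  if (require_significance && (is.na(p_value) || p_value >= alpha)) {
    return("flat")
  }
  if (b < 0) "decay" else if (b > 0) "growth" else "flat"
}

#' Uncertainty-adaptation index for one subject
#'
#' Scalar mediator used in the clinical analyses: the sign-flipped linear
#' slope of the subject's trial-wise uncertainty series, so that larger
#' values mean stronger uncertainty reduction over the task. The
#' alternative operationalization `method = "decay"` uses the sign-flipped
#' exponential rate `-b` instead.
#'
#' @param series trial-wise uncertainty values (e.g.
#'   `latent_series(traj, "uncertainty")`), or a `latent_trajectory` from
#'   which that series is extracted.
#' @param method `"slope"` (default) or `"decay"`.
#' @return list with `index`, `method` and the underlying fit.
#' @export
adaptation_index <- function(series, method = c("slope", "decay")) {
  method <- match.arg(method)
  if (inherits(series, "latent_trajectory")) {
    series <- latent_series(series, "uncertainty")
  }
  fit <- if (method == "slope") linear_slope(series) else exponential_fit(series)
  idx <- if (method == "slope") -fit$slope else -fit$b
  list(index = idx, method = method, fit = fit)
}

#' Per-subject trajectory fits for a cohort
#'
#' Runs the fitted (or generating) model over each subject's data and fits
#' linear and exponential trends to a latent series.
#'
#' @param cohort list of `subject_dataset`s.
#' @param params_by_subject data frame with `subject_id` and native model
#'   parameters (e.g. `fit$models[[m]]$subject_params` from [hbi_fit()]),
#'   or `NULL` to use each dataset's own generating parameters.
#' @param model_id model used for filtering.
#' @param series which latent series to characterize.
#' @param arm `"chosen"` or `"mean"`, see [latent_series()].
#' @param require_significance passed to [classify_trajectory()].
#' @return data frame, one row per subject: slopes, exponential
#'   parameters, time constant, class and adaptation index.
#' @export
fit_trajectories <- function(cohort, params_by_subject = NULL,
                             model_id = "vkf",
                             series = "volatility", arm = "chosen",
                             require_significance = FALSE) {
  do.call(rbind, lapply(cohort, function(ds) {
    pars <- if (is.null(params_by_subject)) {
      attr(ds, "params")
    } else {
      row <- params_by_subject[params_by_subject$subject_id == ds$subject_id, ]
      unlist(row[setdiff(names(row), c("subject_id", "group"))])
    }
    if (is.null(pars)) stop("no parameters available for ", ds$subject_id)
    traj <- run_model(ds, model_id, pars)
    y <- latent_series(traj, series, arm = arm)
    ls <- linear_slope(y)
    ef <- exponential_fit(y)
    data.frame(subject_id = ds$subject_id, group = ds$group, series = series,
               slope = ls$slope, slope_p = ls$p_value,
               a = ef$a, b = ef$b, tau = ef$tau, b_p = ef$p_value,
               r_squared = ef$r_squared,
               class = classify_trajectory(ef$b, ef$p_value,
                                           require_significance),
               adaptation_index = -ls$slope)
  }))
}

#' Group contrasts on trajectory fits
#'
#' Compares two groups' per-subject trajectory characteristics: pooled
#' two-sample t-tests on the linear slopes and on the exponential rates,
#' and Fisher's exact test on the decay-vs-not classification counts.
#'
#' @param fits data frame from [fit_trajectories()] with a `group` column
#'   containing exactly two groups (>= 2 subjects each).
#' @return list with `slope_test`, `decay_rate_test` (each `htest`),
#'   `class_table` and `fisher_test`.
#' @export
group_trajectory_contrast <- function(fits) {
  groups <- unique(fits$group)
  if (length(groups) != 2) stop("need exactly two groups")
  if (any(table(fits$group) < 2)) stop("need >= 2 subjects per group")
  g <- factor(fits$group, levels = groups)
  slope_test <- stats::t.test(slope ~ g, data = fits, var.equal = TRUE)
  decay_rate_test <- stats::t.test(b ~ g, data = fits, var.equal = TRUE)
  decay <- factor(fits$class == "decay", levels = c(TRUE, FALSE),
                  labels = c("decay", "other"))
  tab <- table(g, decay)
  list(slope_test = slope_test, decay_rate_test = decay_rate_test,
       class_table = tab, fisher_test = stats::fisher.test(tab))
}
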