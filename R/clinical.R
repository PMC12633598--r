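# ---- questionnaire statistics and mediation ---------------------------------

#' Extract questionnaire scores from a cohort
#'
#' @param cohort list of `subject_dataset`s whose `scores` are set.
#' @return data frame with `subject_id`, `group` and one column per score.
#' @export
cohort_scores <- function(cohort) {
  do.call(rbind, lapply(cohort, function(ds) {
    if (is.null(ds$scores)) return(NULL)
    cbind(data.frame(subject_id = ds$subject_id, group = ds$group),
          as.data.frame(ds$scores))
  }))
}

#' Two-sample pooled-variance t-test on a score
#'
#' Student's t-test with pooled variance, so the degrees of freedom are
#' `n1 + n2 - 2` (e.g. 63 for groups of 26 and 39).
#'
#' @param x,y numeric score vectors for the two groups (each >= 2
#'   non-missing values with some variance).
#' @return list with `t`, `df`, `p_value`, `mean_diff`.
#' @export
group_ttest <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1,
                mean_diff = 0))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = unname(diff(rev(ht$estimate))) * -1)
}

#' Bootstrap mediation analysis
#'
#' Simple (single-mediator) mediation with OLS paths: `a` from `M ~ X`,
#' `b` and the direct effect `c'` from `Y ~ X + M`, total effect `c` from
#' `Y ~ X`. The indirect effect is `ab` (equal to `c - c'` for these
#' linear models), with a percentile confidence interval from case
#' resampling of whole subjects.
#'
#' @param X binary group indicator (numeric, factor or logical; both
#'   levels required).
#' @param M mediator (e.g. the uncertainty-adaptation index).
#' @param Y outcome (e.g. apathy score).
#' @param n_boot bootstrap replicates (default 5000).
#' @param ci confidence level (default 0.95).
#' @param seed seed for the resampling.
#' @return an object of class `mediation_result`: list with `a`, `b`,
#'   `c`, `c_prime`, `ab`, `ci` (percentile bounds), `significant`
#'   (CI excludes 0), `n`, `n_boot`, `seed`.
#' @export
mediation <- function(X, M, Y, n_boot = 5000, ci = 0.95, seed = 1L) {
  if (is.factor(X) || is.character(X)) X <- as.numeric(factor(X)) - 1
  X <- as.numeric(X)
  cc <- stats::complete.cases(X, M, Y)
  X <- X[cc]; M <- M[cc]; Y <- Y[cc]
  if (length(unique(X)) < 2) stop("X must have both levels")
  if (length(X) < 10) stop("need >= 10 complete cases")

  paths <- function(x, m, y) {
    a <- unname(stats::coef(stats::lm(m ~ x))[2])
    fit_y <- stats::lm(y ~ x + m)
    b <- unname(stats::coef(fit_y)[3])
    c_prime <- unname(stats::coef(fit_y)[2])
    c_tot <- unname(stats::coef(stats::lm(y ~ x))[2])
    c(a = a, b = b, c = c_tot, c_prime = c_prime, ab = a * b)
  }
  est <- paths(X, M, Y)
  boots <- withr::with_seed(seed, {
    n <- length(X)
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(X[idx])) < 2) return(NA_real_)
      unname(paths(X[idx], M[idx], Y[idx])["ab"])
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  alpha <- (1 - ci) / 2
  bounds <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 6))
  structure(list(a = est[["a"]], b = est[["b"]], c = est[["c"]],
                 c_prime = est[["c_prime"]], ab = est[["ab"]],
                 ci = bounds, ci_level = ci,
                 significant = bounds[1] > 0 || bounds[2] < 0,
                 n = length(X), n_boot = n_boot, seed = seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation> a=%.3f b=%.3f c=%.3f c'=%.3f ab=%.3f, %d%% CI [%.3f, %.3f] (%s), n=%d\n",
    x$a, x$b, x$c, x$c_prime, x$ab, round(100 * x$ci_level),
    x$ci[1], x$ci[2], if (x$significant) "significant" else "n.s.", x$n))
  invisible(x)
}

#' Flag implausible pain reports in the no-pain group
#'
#' Outlier screen for two-group designs: subjects in the nominally
#' pain-free group reporting a visual-analogue pain score above
#' `threshold` are flagged (for example a control reporting VAS 68/100
#' despite no diagnosed pain condition). The screen only flags; exclusion
#' is the caller's decision.
#'
#' @param scores data frame with `group` and `vas` columns (see
#'   [cohort_scores()]).
#' @param no_pain_group label of the group expected to be pain-free.
#' @param threshold VAS cut-off (0-100 scale).
#' @return logical vector, `TRUE` for flagged subjects.
#' @export
flag_vas_outliers <- function(scores, no_pain_group = "HC", threshold = 60) {
  if (!all(c("group", "vas") %in% names(scores))) {
    stop("scores needs 'group' and 'vas' columns")
  }
  scores$group == no_pain_group & !is.na(scores$vas) & scores$vas > threshold
}

#' Control correlations against pain-severity grade
#'
#' Pearson correlations (with p-values) between a severity measure such as
#' the GCPS grade (coerced to its numeric level) and a set of indices:
#' typically the adaptation index and the questionnaire battery.
#'
#' @param severity numeric vector, or ordered factor / roman-numeral
#'   character grades.
#' @param indices named list or data frame of numeric vectors.
#' @return data frame with `measure`, `r`, `p_value`, `n`; degenerate
#'   pairs yield `NA` rows.
#' @export
control_correlations <- function(severity, indices) {
  if (is.character(severity) || is.factor(severity)) {
    severity <- match(as.character(severity), c("I", "II", "III", "IV"))
  }
  indices <- as.data.frame(indices)
  do.call(rbind, lapply(names(indices), function(nm) {
    y <- as.numeric(indices[[nm]])
    cc <- stats::complete.cases(severity, y)
    if (sum(cc) < 3 || stats::sd(severity[cc]) == 0 || stats::sd(y[cc]) == 0) {
      return(data.frame(measure = nm, r = NA_real_, p_value = NA_real_,
                        n = sum(cc)))
    }
    ht <- stats::cor.test(severity[cc], y[cc])
    data.frame(measure = nm, r = unname(ht$estimate), p_value = ht$p.value,
               n = sum(cc))
  }))
}
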