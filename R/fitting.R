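# ---- subject-level MAP with Laplace evidence --------------------------------

neg_log_joint <- function(theta, dataset, model_id, spec, prior_mean, prior_sd,
                          m0 = 0.5, w0 = NULL) {
  params <- theta_to_native(theta, spec)
  nll <- tryCatch(
    negative_log_likelihood(dataset, model_id, params, m0 = m0, w0 = w0),
    error = function(e) Inf)
  if (!is.finite(nll)) return(1e10)
  nll - sum(stats::dnorm(theta, prior_mean, prior_sd, log = TRUE))
}

# diagonal of the Laplace posterior covariance (inverse Hessian of the
# negative log joint); falls back to 1/diag when the solve fails
posterior_var_diag <- function(H) {
  d <- nrow(H)
  pv <- tryCatch(diag(solve(H)), error = function(e) 1 / pmax(diag(H), 1e-8))
  pv[!is.finite(pv) | pv <= 0] <- 1 / pmax(diag(H)[!is.finite(pv) | pv <= 0], 1e-8)
  pmin(pmax(pv, 1e-8), 1e2)
}

# log-determinant of a (possibly ill-conditioned) Hessian; adds a ridge
# until Cholesky succeeds. Returns list(logdet, jittered)
safe_logdet <- function(H) {
  d <- nrow(H)
  jit <- 0
  for (i in 0:8) {
    R <- tryCatch(chol(H + diag(jit, d)), error = function(e) NULL)
    if (!is.null(R)) {
      return(list(logdet = 2 * sum(log(diag(R))), jittered = jit > 0))
    }
    jit <- if (jit == 0) 1e-6 else jit * 10
  }
  list(logdet = d * log(1e6), jittered = TRUE)
}

#' MAP fit of one subject under a Gaussian prior in transformed space
#'
#' Maximizes log-likelihood plus log-prior over the model's free
#' parameters in transformed space (sigmoid/exponential mappings) with
#' multi-start BFGS, and computes the Laplace approximation to the model
#' evidence: `logLik + logPrior` at the mode plus `d/2 log(2*pi) - 1/2
#' log det H`, where `H` is the curvature of the negative log joint.
#'
#' @param dataset a `subject_dataset` with at least one valid trial.
#' @param model_id model identifier.
#' @param prior list with `mean` and `var` (scalars or per-parameter
#'   vectors) in transformed space; defaults to the 0 / 6.25 initial prior.
#' @param n_starts number of optimizer starts; the first is the prior
#'   mean, the rest are drawn from the prior.
#' @param fixed optional named list of parameters clamped at native values.
#' @param seed seed for the start draws.
#' @param m0,w0 initial latent conditions, see [run_model()].
#' @return list with `theta` (transformed optimum), `params` (native,
#'   including clamps), `nll`, `log_evidence`, `hessian`, `converged`.
#' @export
map_fit_subject <- function(dataset, model_id, prior = list(mean = 0, var = 6.25),
                            n_starts = 10, fixed = NULL, seed = 1L,
                            m0 = 0.5, w0 = NULL) {
  if (n_valid_trials(dataset) < 1) stop("dataset has no valid trials")
  spec <- param_transform_spec(model_id, fixed = fixed)
  d <- nrow(spec)
  prior_mean <- rep(prior$mean, length.out = d)
  prior_sd <- sqrt(rep(prior$var, length.out = d))

  starts <- withr::with_seed(seed, {
    s <- matrix(stats::rnorm(n_starts * d, prior_mean, prior_sd),
                n_starts, d, byrow = TRUE)
    s[1, ] <- prior_mean
    s
  })
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], neg_log_joint, dataset = dataset,
                   model_id = model_id, spec = spec, prior_mean = prior_mean,
                   prior_sd = prior_sd, m0 = m0, w0 = w0,
                   method = "BFGS", control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(list(theta = rep(NA_real_, d), params = NULL, nll = NA_real_,
                log_evidence = -Inf, hessian = NULL, converged = FALSE))
  }
  H <- tryCatch(
    stats::optimHess(best$par, neg_log_joint, dataset = dataset,
                     model_id = model_id, spec = spec, prior_mean = prior_mean,
                     prior_sd = prior_sd, m0 = m0, w0 = w0),
    error = function(e) diag(1, d))
  ld <- safe_logdet(H)
  params <- theta_to_native(best$par, spec)
  structure(list(
    theta = stats::setNames(best$par, spec$name),
    params = params,
    nll = negative_log_likelihood(dataset, model_id, params, m0 = m0, w0 = w0),
    log_evidence = -best$value + 0.5 * d * log(2 * pi) - 0.5 * ld$logdet,
    hessian = H,
    converged = best$convergence == 0 && !ld$jittered
  ), class = "subject_fit")
}

# one subject refit from a list of transformed-space starts: best optimum
# kept, a single Hessian evaluated at it for the Laplace evidence
refit_subject <- function(dataset, model_id, spec, prior, starts) {
  pm <- prior$mean; ps <- sqrt(prior$var)
  d <- nrow(spec)
  best <- NULL
  for (s in starts) {
    f <- tryCatch(
      stats::optim(s, neg_log_joint, dataset = dataset, model_id = model_id,
                   spec = spec, prior_mean = pm, prior_sd = ps,
                   method = "BFGS", control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(f) && is.finite(f$value) &&
        (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) {
    return(list(theta = rep(NA_real_, d), params = NULL, nll = NA_real_,
                log_evidence = -Inf, hessian = NULL, converged = FALSE))
  }
  H <- tryCatch(
    stats::optimHess(best$par, neg_log_joint, dataset = dataset,
                     model_id = model_id, spec = spec, prior_mean = pm,
                     prior_sd = ps),
    error = function(e) diag(1, d))
  ld <- safe_logdet(H)
  list(theta = stats::setNames(best$par, spec$name),
       params = theta_to_native(best$par, spec),
       nll = NA_real_,
       log_evidence = -best$value + 0.5 * d * log(2 * pi) - 0.5 * ld$logdet,
       hessian = H,
       converged = best$convergence == 0 && !ld$jittered)
}

# ---- hierarchical (empirical-Bayes) fitting ---------------------------------

#' Hierarchical Bayesian fitting of candidate models to a cohort
#'
#' Self-contained hierarchical inference in the spirit of random-effects
#' model comparison toolboxes: subjects are fit by MAP under empirical
#' Gaussian priors in transformed space, the group-level prior of each
#' model is re-estimated from the subject optima weighted by per-subject
#' model responsibilities (computed from Laplace evidences), and the loop
#' repeats until the group means stabilize. Initialization is the
#' non-hierarchical MAP stage with the 0 / 6.25 prior.
#'
#' @param cohort list of `subject_dataset`s (>= 2 subjects).
#' @param model_ids character vector of candidate models.
#' @param fixed optional named list of clamped parameters (applied to every
#'   model that has them).
#' @param n_starts starts for the initial MAP stage.
#' @param n_starts_refit starts per hierarchical refit in addition to the
#'   warm start from the previous optimum; the default single start is the
#'   current group mean, keeping refits deterministic, and larger values
#'   add fresh prior draws.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   transformed group means.
#' @param max_iter outer-iteration cap; non-convergence returns the best
#'   iterate, flagged.
#' @param var_floor lower bound on empirical prior variances.
#' @param seed master seed (start draws and the exceedance-probability
#'   Monte Carlo).
#' @param xp_samples Monte-Carlo sample count for exceedance probabilities.
#' @return an object of class `hbi_fit`: list with per-model elements
#'   (`subject_params` native-space data frame, `theta` matrix,
#'   `group_mean` native and transformed, `hierarchical_error`,
#'   `log_evidence` vector), a `responsibilities` matrix, and a
#'   `comparison` data frame (model frequencies and exceedance
#'   probabilities).
#' @export
hbi_fit <- function(cohort, model_ids = "vkf", fixed = NULL,
                    n_starts = 10, n_starts_refit = 1,
                    tol = 1e-3, max_iter = 50, var_floor = 0.01,
                    seed = 1L, xp_samples = 1e5) {
  n_sub <- length(cohort)
  if (n_sub < 2) stop("hbi_fit needs at least 2 subjects")
  n_mod <- length(model_ids)
  specs <- lapply(model_ids, function(m) {
    fx <- fixed[intersect(names(fixed), model_param_names(m))]
    if (!length(fx)) fx <- NULL
    param_transform_spec(m, fixed = fx)
  })
  names(specs) <- model_ids
  seeds <- withr::with_seed(seed, matrix(
    sample.int(.Machine$integer.max, n_sub * n_mod * (max_iter + 1L)),
    nrow = n_sub * n_mod))

  # stage 0: independent MAP under the wide initial prior
  fits <- vector("list", n_mod); names(fits) <- model_ids
  for (mi in seq_len(n_mod)) {
    m <- model_ids[mi]
    fits[[m]] <- lapply(seq_len(n_sub), function(si) {
      map_fit_subject(cohort[[si]], m, n_starts = n_starts,
                      fixed = attr(specs[[m]], "fixed"),
                      seed = seeds[(mi - 1L) * n_sub + si, 1L])
    })
  }
  get_L <- function(fits) {
    vapply(model_ids, function(m)
      vapply(fits[[m]], `[[`, 0, "log_evidence"), numeric(n_sub))
  }
  resp_from_L <- function(L) {
    R <- exp(L - apply(L, 1, max))
    R / rowSums(R)
  }
  L <- matrix(get_L(fits), n_sub, n_mod, dimnames = list(NULL, model_ids))
  resp <- resp_from_L(L)

  # group prior update: responsibility-weighted mean, and a variance that
  # combines the spread of the subject optima with their Laplace posterior
  # variances (without the latter the empirical prior collapses and
  # over-shrinks weakly identified parameters)
  update_group <- function(fit_list, r) {
    th <- do.call(rbind, lapply(fit_list, `[[`, "theta"))
    pv <- do.call(rbind, lapply(fit_list, function(f)
      if (is.null(f$hessian)) rep(1, ncol(th)) else posterior_var_diag(f$hessian)))
    bad <- apply(th, 1, function(x) any(!is.finite(x)))
    if (any(bad)) {
      r[bad] <- 0
      th[bad, ] <- 0
      pv[bad, ] <- 1
    }
    if (sum(r) < 1e-8) r <- rep(1e-8, length(r))
    mu <- colSums(th * r) / sum(r)
    vv <- colSums((t(t(th) - mu)^2 + pv) * r) / sum(r)
    list(mean = mu, var = pmax(vv, var_floor), weight = sum(r))
  }
  group <- lapply(seq_len(n_mod), function(mi)
    update_group(fits[[model_ids[mi]]], resp[, mi]))
  names(group) <- model_ids

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    old_means <- lapply(group, `[[`, "mean")
    for (mi in seq_len(n_mod)) {
      m <- model_ids[mi]
      pr <- list(mean = group[[m]]$mean, var = group[[m]]$var)
      draw_seeds <- seeds[, it + 1L]
      fits[[m]] <- lapply(seq_len(n_sub), function(si) {
        warm <- fits[[m]][[si]]$theta
        starts <- list()
        if (!any(is.na(warm))) starts <- list(unname(warm))
        if (n_starts_refit >= 1) starts <- c(starts, list(pr$mean))
        if (n_starts_refit >= 2) {
          extra <- withr::with_seed(draw_seeds[(mi - 1L) * n_sub + si],
            matrix(stats::rnorm((n_starts_refit - 1L) * nrow(specs[[m]]),
                                pr$mean, sqrt(pr$var)),
                   n_starts_refit - 1L, byrow = TRUE))
          starts <- c(starts, lapply(seq_len(nrow(extra)),
                                     function(i) extra[i, ]))
        }
        refit_subject(cohort[[si]], m, specs[[m]], pr, starts)
      })
    }
    L <- matrix(get_L(fits), n_sub, n_mod, dimnames = list(NULL, model_ids))
    resp <- resp_from_L(L)
    for (mi in seq_len(n_mod)) {
      group[[model_ids[mi]]] <- update_group(fits[[model_ids[mi]]], resp[, mi])
    }
    delta <- max(vapply(model_ids, function(m)
      max(abs(group[[m]]$mean - old_means[[m]])), numeric(1)))
    if (delta < tol) { converged <- TRUE; break }
  }

  models <- lapply(seq_len(n_mod), function(mi) {
    m <- model_ids[mi]
    th <- do.call(rbind, lapply(fits[[m]], `[[`, "theta"))
    all_names <- model_param_names(m)
    pars <- do.call(rbind, lapply(fits[[m]], function(f) {
      if (is.null(f$params)) {
        as.data.frame(as.list(stats::setNames(rep(NA_real_, length(all_names)),
                                              all_names)))
      } else {
        as.data.frame(as.list(f$params))
      }
    }))
    pars <- cbind(subject_id = vapply(cohort, function(s) s$subject_id, ""),
                  pars)
    w <- sum(resp[, mi])
    list(
      model_id = m,
      subject_params = pars,
      theta = th,
      group_mean_transformed = group[[m]]$mean,
      group_var_transformed = group[[m]]$var,
      group_mean = theta_to_native(group[[m]]$mean, specs[[m]]),
      hierarchical_error = sqrt(group[[m]]$var / max(w, 1)),
      log_evidence = L[, mi],
      converged = vapply(fits[[m]], `[[`, TRUE, "converged"))
  })
  names(models) <- model_ids

  bms <- exceedance_probability(L, n_samples = xp_samples,
                                seed = seeds[1L, 1L] %% .Machine$integer.max)
  comparison <- data.frame(model_id = model_ids,
                           sum_log_evidence = colSums(L),
                           frequency = bms$frequency,
                           xp = bms$xp)
  structure(list(models = models, responsibilities = resp,
                 log_evidence = L, comparison = comparison,
                 converged = converged,
                 winning_model = model_ids[which.max(bms$xp)]),
            class = "hbi_fit")
}

#' @export
print.hbi_fit <- function(x, ...) {
  cat("<hbi_fit>", nrow(x$responsibilities), "subjects,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

# ---- random-effects model comparison ----------------------------------------

#' Exceedance probabilities from per-subject model evidence
#'
#' Random-effects Bayesian model selection: model frequencies in the
#' population get a Dirichlet prior (`alpha0` per model), the posterior
#' Dirichlet weights are estimated by the standard variational scheme from
#' the subject-wise log evidences, and the exceedance probability of each
#' model — the posterior probability that it is the most frequent model —
#' is estimated by Monte-Carlo sampling from the posterior Dirichlet.
#'
#' @param log_evidence numeric matrix, subjects x models.
#' @param alpha0 Dirichlet prior count per model.
#' @param n_samples Monte-Carlo draws for the exceedance computation.
#' @param seed seed for the Monte-Carlo draws.
#' @return list with `alpha` (posterior Dirichlet weights), `frequency`
#'   (expected model frequencies) and `xp` (exceedance probabilities,
#'   summing to 1 up to Monte-Carlo error).
#' @export
exceedance_probability <- function(log_evidence, alpha0 = 1,
                                   n_samples = 1e5, seed = 1L) {
  L <- as.matrix(log_evidence)
  if (any(!is.finite(L))) {
    L[!is.finite(L)] <- min(L[is.finite(L)]) - 100
  }
  n_mod <- ncol(L)
  if (n_mod == 1L) {
    return(list(alpha = alpha0 + nrow(L), frequency = 1, xp = 1))
  }
  alpha <- rep(alpha0, n_mod)
  for (i in 1:200) {
    lw <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- exp(lw - apply(lw, 1, max))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < 1e-8) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  xp <- withr::with_seed(seed, {
    g <- matrix(stats::rgamma(n_samples * n_mod, shape = rep(alpha, each = n_samples)),
                n_samples, n_mod)
    win <- max.col(g, ties.method = "random")
    tabulate(win, n_mod) / n_samples
  })
  list(alpha = alpha, frequency = alpha / sum(alpha), xp = xp)
}
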