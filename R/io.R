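# ---- CSV serialization ------------------------------------------------------

#' Write a cohort to CSV
#'
#' One row per trial with columns `subject_id`, `group`, `trial`, `choice`,
#' `outcome`, `rt`, `valid` and, when schedules are attached, the per-arm
#' scheduled probabilities `p_arm1..p_armK` (arm indices 1-based).
#' Questionnaire scores, when present, go to a companion file
#' (`<path base>_scores.csv`).
#'
#' @param cohort list of `subject_dataset`s.
#' @param path output CSV path for the trial table.
#' @param scores_path optional explicit path for the scores table.
#' @return invisibly, the path(s) written.
#' @export
write_cohort <- function(cohort, path, scores_path = NULL) {
  rows <- do.call(rbind, lapply(cohort, function(ds) {
    tr <- ds$trials
    out <- data.frame(subject_id = ds$subject_id, group = ds$group,
                      trial = tr$trial, choice = tr$choice,
                      outcome = tr$outcome, rt = tr$rt, valid = tr$valid)
    if (!is.null(ds$schedule)) {
      p <- ds$schedule$probs[tr$trial, , drop = FALSE]
      colnames(p) <- paste0("p_arm", seq_len(ncol(p)))
      out <- cbind(out, p)
    }
    out
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  paths <- path
  sc <- cohort_scores(cohort)
  if (!is.null(sc) && nrow(sc)) {
    if (is.null(scores_path)) {
      scores_path <- sub("\\.csv$", "_scores.csv", path)
    }
    utils::write.csv(sc, scores_path, row.names = FALSE)
    paths <- c(paths, scores_path)
  }
  invisible(paths)
}

#' Load a cohort from CSV
#'
#' Reads a trial table written by [write_cohort()] (or any CSV with the
#' required columns `subject_id`, `group`, `trial`, `choice`, `outcome`;
#' optional `rt`, `valid`, `p_arm1..p_armK`). When no `valid` column is
#' present, validity is derived: a trial is invalid if the choice is
#' missing or the response took longer than `rt_cutoff` seconds.
#'
#' @param path trial-table CSV.
#' @param scores_path optional scores CSV with `subject_id` plus score
#'   columns; defaults to `<path base>_scores.csv` when that file exists.
#' @param rt_cutoff response deadline in seconds.
#' @return a `cohort` (list of `subject_dataset`s).
#' @export
load_cohort <- function(path, scores_path = NULL, rt_cutoff = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "trial", "choice", "outcome")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cohort CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  p_cols <- grep("^p_arm[0-9]+$", names(df), value = TRUE)
  n_arms <- if (length(p_cols)) length(p_cols) else
    max(df$choice, na.rm = TRUE)
  if (is.null(scores_path)) {
    cand <- sub("\\.csv$", "_scores.csv", path)
    if (file.exists(cand)) scores_path <- cand
  }
  scores <- if (!is.null(scores_path))
    utils::read.csv(scores_path, stringsAsFactors = FALSE) else NULL

  subjects <- lapply(split(df, df$subject_id), function(sub) {
    sub <- sub[order(sub$trial), , drop = FALSE]
    if (any(diff(sub$trial) != 1)) {
      warning("non-contiguous trial indices for subject ", sub$subject_id[1])
    }
    schedule <- NULL
    if (length(p_cols)) {
      probs <- as.matrix(sub[, p_cols, drop = FALSE])
      colnames(probs) <- paste0("arm", seq_len(ncol(probs)))
      schedule <- structure(
        list(probs = probs, step_size = NA_real_, step_prob = NA_real_,
             bounds = range(probs), seed = NA_integer_),
        class = "reward_schedule")
    }
    sc <- NULL
    if (!is.null(scores)) {
      row <- scores[scores$subject_id == sub$subject_id[1], , drop = FALSE]
      if (nrow(row)) sc <- as.list(row[, setdiff(names(row),
                                                 c("subject_id", "group")),
                                       drop = FALSE])
    }
    subject_dataset(sub[, intersect(c("trial", "choice", "outcome", "rt", "valid"),
                                    names(sub))],
                    n_arms = n_arms,
                    subject_id = sub$subject_id[1], group = sub$group[1],
                    schedule = schedule, scores = sc, rt_cutoff = rt_cutoff)
  })
  # preserve file order of subjects
  subjects <- subjects[unique(df$subject_id)]
  structure(subjects, class = "cohort")
}

#' Save / load a cohort specification as JSON
#'
#' @param spec a [cohort_spec()].
#' @param path JSON file path.
#' @return `write_cohort_spec` returns the path invisibly;
#'   `read_cohort_spec` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(x$groups, function(g) {
    g$dist <- lapply(g$dist, as.numeric)
    g
  })
  cohort_spec(groups = groups, n_trials = x$n_trials, n_arms = x$n_arms,
              step_prob = x$step_prob, step_size = x$step_size,
              bounds = as.numeric(x$bounds),
              apathy_base = x$apathy_base,
              apathy_group_effect = x$apathy_group_effect,
              apathy_loading = x$apathy_loading,
              apathy_noise_sd = x$apathy_noise_sd,
              seed = x$seed)
}

#' Export a latent trajectory to long-format CSV
#'
#' One row per valid trial and arm: `subject_id`, `trial`, `arm`, `m`,
#' `w`, `v` (where the model defines them), plus the chosen-arm `k`,
#' `rv`, `ru` and `logp` repeated per trial.
#'
#' @param trajectory a `latent_trajectory` from [run_model()].
#' @param path output CSV path.
#' @param subject_id identifier written into the table.
#' @return invisibly, the long-format data frame written.
#' @export
write_trajectory <- function(trajectory, path, subject_id = "s1") {
  arms <- grep("^m\\.arm", names(trajectory), value = TRUE)
  n_arms <- length(arms)
  long <- do.call(rbind, lapply(seq_len(n_arms), function(a) {
    out <- data.frame(subject_id = subject_id,
                      trial = trajectory$trial, arm = a,
                      m = trajectory[[paste0("m.arm", a)]])
    wcol <- paste0("w.arm", a); vcol <- paste0("v.arm", a)
    out$w <- if (wcol %in% names(trajectory)) trajectory[[wcol]] else NA_real_
    out$v <- if (vcol %in% names(trajectory)) trajectory[[vcol]] else NA_real_
    out$k <- trajectory$k
    out$rv <- trajectory$rv
    out$ru <- trajectory$ru
    out$logp <- trajectory$logp
    out
  }))
  long <- long[order(long$trial, long$arm), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(long)
}

# ---- pipeline orchestration -------------------------------------------------

#' Pipeline configuration with study defaults
#'
#' Validated settings for [run_pipeline()]: 200 trials, 3 arms, 10% step
#' chance with step size 0.1 and bounds 0.1-0.9, the 0/6.25 transformed-
#' space prior, the four candidate models, and a 5000-sample bootstrap for
#' mediation.
#'
#' @param cohort a `cohort` to analyse, or `NULL` to simulate one from
#'   `spec`.
#' @param spec a [cohort_spec()] used when `cohort` is `NULL`.
#' @param model_list candidate models for fitting and comparison.
#' @param n_starts,n_starts_refit,tol,max_iter fitting settings, see
#'   [hbi_fit()].
#' @param series latent series used for trajectory analysis and the
#'   mediator.
#' @param per_group_fit refit the winning model separately within each
#'   group before trajectory analysis (default `TRUE`). Shrinkage towards
#'   a pooled population mean can mask genuine group differences in
#'   weakly identified parameters; per-group empirical priors shrink
#'   within, not across, groups.
#' @param mediator_method `"slope"` or `"decay"`, see [adaptation_index()].
#' @param outcome questionnaire score mediated to (default `"ami"`).
#' @param n_boot,ci_level mediation bootstrap settings.
#' @param seed master seed.
#' @param out_dir optional directory for CSV/JSON outputs (created if
#'   needed); `NULL` keeps results in memory only.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, spec = cohort_spec(),
                            model_list = c("rw1", "rw2", "kf", "vkf"),
                            n_starts = 10, n_starts_refit = 3,
                            tol = 1e-3, max_iter = 50,
                            series = "uncertainty",
                            per_group_fit = TRUE,
                            mediator_method = "slope",
                            outcome = "ami",
                            n_boot = 5000, ci_level = 0.95,
                            seed = 1L, out_dir = NULL) {
  unknown <- setdiff(model_list, model_ids())
  if (length(unknown)) stop("unknown model name(s): ",
                            paste(unknown, collapse = ", "))
  if (!series %in% c("volatility", "uncertainty", "learning_rate")) {
    stop("series must be volatility, uncertainty or learning_rate")
  }
  structure(list(cohort = cohort, spec = spec, model_list = model_list,
                 n_starts = n_starts, n_starts_refit = n_starts_refit,
                 tol = tol, max_iter = max_iter, series = series,
                 per_group_fit = per_group_fit,
                 mediator_method = mediator_method, outcome = outcome,
                 n_boot = n_boot, ci_level = ci_level,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate or take a cohort, compute model-free
#' metrics, fit and compare the candidate models hierarchically, extract
#' latent trajectories under the winning model, contrast the groups'
#' trajectory characteristics, and run the mediation analysis from group
#' through the adaptation index to the configured outcome score. Any
#' stage failure is recorded in the manifest and downstream stages are
#' skipped with a reason.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_bundle`: list with `metrics`, `fit`, `comparison`,
#'   `trajectories`, `contrast`, `mediation`, `scores` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed, models = config$model_list,
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   package_version = as.character(utils::packageVersion("vkfbandit")),
                   stages = list())
  bundle <- list(manifest = manifest)
  failed <- NULL

  stage <- function(name, expr) {
    if (!is.null(failed)) {
      bundle$manifest$stages[[name]] <<- list(status = "skipped",
                                              reason = paste("after failure in", failed))
      return(NULL)
    }
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      failed <<- name
      bundle$manifest$stages[[name]] <<- list(status = "error",
                                              message = conditionMessage(out))
      return(NULL)
    }
    bundle$manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[3] - t0, 2))
    out
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort)) config$cohort else {
      sp <- config$spec
      sp$seed <- config$seed
      simulate_cohort(sp)
    }
  })
  bundle$metrics <- stage("metrics", cohort_metrics(cohort))
  bundle$fit <- stage("fit", hbi_fit(cohort, model_ids = config$model_list,
                                     n_starts = config$n_starts,
                                     n_starts_refit = config$n_starts_refit,
                                     tol = config$tol,
                                     max_iter = config$max_iter,
                                     seed = config$seed))
  bundle$comparison <- if (!is.null(bundle$fit)) bundle$fit$comparison
  bundle$trajectories <- stage("trajectories", {
    win <- bundle$fit$winning_model
    pars <- if (isTRUE(config$per_group_fit)) {
      groups <- vapply(cohort, `[[`, "", "group")
      do.call(rbind, lapply(unique(groups), function(g) {
        sub <- cohort[groups == g]
        gf <- hbi_fit(sub, model_ids = win, n_starts = config$n_starts,
                      n_starts_refit = config$n_starts_refit,
                      tol = config$tol, max_iter = config$max_iter,
                      seed = config$seed, xp_samples = 1e3)
        gf$models[[win]]$subject_params
      }))
    } else {
      bundle$fit$models[[win]]$subject_params
    }
    fit_trajectories(cohort, params_by_subject = pars,
                     model_id = win, series = config$series)
  })
  bundle$contrast <- stage("contrast", group_trajectory_contrast(bundle$trajectories))
  bundle$scores <- stage("scores", cohort_scores(cohort))
  bundle$mediation <- stage("mediation", {
    sc <- bundle$scores
    tj <- bundle$trajectories
    m <- tj$adaptation_index[match(sc$subject_id, tj$subject_id)]
    groups <- unique(sc$group)
    mediation(X = as.numeric(sc$group == groups[2]), M = m,
              Y = sc[[config$outcome]], n_boot = config$n_boot,
              ci = config$ci_level, seed = config$seed)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(config$out_dir, f), row.names = FALSE)
    w(bundle$metrics, "metrics.csv")
    w(bundle$comparison, "model_comparison.csv")
    w(bundle$trajectories, "trajectories.csv")
    w(bundle$scores, "scores.csv")
    if (!is.null(bundle$mediation)) {
      jsonlite::write_json(
        bundle$mediation[c("a", "b", "c", "c_prime", "ab", "ci", "n",
                           "n_boot", "seed")],
        file.path(config$out_dir, "mediation.json"), auto_unbox = TRUE,
        digits = NA)
    }
    jsonlite::write_json(bundle$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  class(bundle) <- "pipeline_bundle"
  bundle
}

#' Human-readable summary of a pipeline run
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @return character vector of report lines (also usable with `cat`).
#' @export
make_report <- function(bundle) {
  if (is.null(bundle) || !length(setdiff(names(bundle), "manifest"))) {
    return("no results")
  }
  lines <- c("== Restless-bandit analysis report ==", "")
  if (!is.null(bundle$comparison)) {
    lines <- c(lines, "Model comparison (frequency / exceedance probability):",
               sprintf("  %-8s freq=%.3f xp=%.3f", bundle$comparison$model_id,
                       bundle$comparison$frequency, bundle$comparison$xp), "")
  }
  if (!is.null(bundle$contrast)) {
    st <- bundle$contrast$slope_test
    ft <- bundle$contrast$fisher_test
    lines <- c(lines, sprintf(
      "Trajectory slopes: t = %.2f, p = %.4g; decay-class Fisher p = %.4g",
      st$statistic, st$p.value, ft$p.value), "")
  }
  if (!is.null(bundle$mediation)) {
    m <- bundle$mediation
    lines <- c(lines, sprintf(
      "Mediation: ab = %.3f, %d%% CI [%.3f, %.3f] (%s)",
      m$ab, round(100 * m$ci_level), m$ci[1], m$ci[2],
      if (m$significant) "significant" else "n.s."), "")
  }
  if (!is.null(bundle$metrics)) {
    lines <- c(lines, sprintf(
      "Model-free: mean win-stay %.3f, mean best-option rate %.3f over %d subjects",
      mean(bundle$metrics$win_stay, na.rm = TRUE),
      mean(bundle$metrics$best_option_rate, na.rm = TRUE),
      nrow(bundle$metrics)))
  }
  lines
}
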