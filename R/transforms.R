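# Parameter transforms between native (constrained) and unconstrained space.
# Unit-range parameters use the sigmoid, positive parameters the exponential;
# fitting and hierarchical summaries operate in the unconstrained space with
# a N(0, 6.25) initial prior on every coordinate.

#' Transform specification for a model's parameters
#'
#' @param model_id model identifier, see [model_ids()].
#' @param fixed optional named list of parameters to clamp at fixed native
#'   values; clamped parameters are removed from the free set.
#' @param prior_mean,prior_var initial prior location and variance in
#'   transformed space (defaults 0 and 6.25).
#' @return a `param_transform_spec`: data frame with columns `name`,
#'   `constraint`, `prior_mean`, `prior_var`, plus the clamp list in
#'   `attr(, "fixed")`.
#' @export
param_transform_spec <- function(model_id, fixed = NULL,
                                 prior_mean = 0, prior_var = 6.25) {
  info <- model_info(model_id)
  nm <- names(info$params)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), nm)
    if (length(bad)) stop("cannot fix unknown parameter(s): ",
                          paste(bad, collapse = ", "))
    nm <- setdiff(nm, names(fixed))
    if (!length(nm)) stop("all parameters fixed; nothing to fit")
  }
  spec <- data.frame(name = nm, constraint = unname(info$params[nm]),
                     prior_mean = prior_mean, prior_var = prior_var,
                     stringsAsFactors = FALSE)
  attr(spec, "model_id") <- model_id
  attr(spec, "fixed") <- fixed
  class(spec) <- c("param_transform_spec", "data.frame")
  spec
}

#' Map transformed parameters to native space
#'
#' Sigmoid for unit-range parameters, exponential for positive ones;
#' clamped parameters from the spec are appended at their fixed values.
#'
#' @param theta numeric vector in transformed space (free parameters, in
#'   spec order).
#' @param spec a [param_transform_spec()].
#' @return named native parameter vector including any clamped values.
#' @export
theta_to_native <- function(theta, spec) {
  out <- ifelse(spec$constraint == "unit", stats::plogis(theta), exp(theta))
  names(out) <- spec$name
  fixed <- attr(spec, "fixed")
  if (!is.null(fixed)) out <- c(out, unlist(fixed))
  model_id <- attr(spec, "model_id")
  if (!is.null(model_id)) out <- out[names(model_info(model_id)$params)]
  out
}

#' Map native parameters to transformed space
#'
#' Inverse of [theta_to_native()] on the free parameters.
#'
#' @param params named native parameter vector.
#' @param spec a [param_transform_spec()].
#' @return numeric vector in transformed space (free parameters only).
#' @export
native_to_theta <- function(params, spec) {
  params <- unlist(params)
  vapply(seq_len(nrow(spec)), function(i) {
    x <- params[[spec$name[i]]]
    if (spec$constraint[i] == "unit") stats::qlogis(x) else log(x)
  }, numeric(1))
}
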