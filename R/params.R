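#' Model parameter vectors
#'
#' Construct and validate a parameter vector for one of the four cognitive
#' models of cWCST performance:
#' \describe{
#'   \item{\code{"wprl"}}{weighted parallel reinforcement learning: category
#'     (model-based) and response (model-free) learning in parallel, with a
#'     weighting parameter \code{w} arbitrating between the two value
#'     systems (8 parameters).}
#'   \item{\code{"prl"}}{parallel reinforcement learning: unweighted sum of
#'     the two value systems (7 parameters).}
#'   \item{\code{"mbrl"}}{model-based only (4 parameters).}
#'   \item{\code{"au"}}{attentional updating: an attention vector over the
#'     three sorting categories, updated multiplicatively by feedback
#'     (4 parameters).}
#' }
#'
#' Learning rates (\code{alpha_*}), inertia (\code{gamma_*}), the weighting
#' \code{w} and the AU updating ratios (\code{p_pos}, \code{p_neg}) live in
#' \eqn{[0, 1]}; the softmax temperature \code{tau}, the attentional focus
#' \code{f} and the decision consistency \code{d} live in \eqn{(0, 5]}.
#'
#' @param model one of \code{"wprl"}, \code{"prl"}, \code{"mbrl"},
#'   \code{"au"}.
#' @param ... named parameter values (see Details); all parameters of the
#'   chosen model must be supplied.
#' @param reduced for \code{model = "au"} only: the reduced AU variant with
#'   the attentional focus fixed at \code{f = 1} and \code{p_pos} fixed at
#'   0.9999 (only \code{p_neg} and \code{d} are free).
#' @return an object of class \code{"wcst_params"}: a named numeric vector
#'   of constrained parameter values with attributes \code{model} and
#'   \code{reduced}.
#' @examples
#' wcst_params("mbrl", alpha_mb_pos = 0.99, alpha_mb_neg = 0.6,
#'             gamma_mb = 0.3, tau = 0.1)
#' @export
wcst_params <- function(model = c("wprl", "prl", "mbrl", "au"), ...,
                        reduced = FALSE) {
  model <- match.arg(model)
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) &&
      (is.numeric(vals[[1L]]) && length(vals[[1L]]) > 1L))
    vals <- as.list(vals[[1L]])
  nm <- wcst_param_names(model)
  if (reduced) {
    if (model != "au") stopf("`reduced` applies to the AU model only")
    vals$f <- vals$f %||% 1
    vals$p_pos <- vals$p_pos %||% 0.9999
  }
  missing <- setdiff(nm, names(vals))
  if (length(missing))
    stopf("missing parameter(s) for %s model: %s", model,
          paste(missing, collapse = ", "))
  extra <- setdiff(names(vals), nm)
  if (length(extra))
    stopf("unknown parameter(s) for %s model: %s", model,
          paste(extra, collapse = ", "))
  p <- vapply(nm, function(k) as.numeric(vals[[k]]), numeric(1))
  kinds <- wcst_param_kinds(model)
  for (k in nm) {
    if (!is.finite(p[[k]])) stopf("parameter %s must be finite", k)
    if (kinds[[k]] == "unit") {
      if (p[[k]] < 0 || p[[k]] > 1)
        stopf("parameter %s must lie in [0, 1], got %g", k, p[[k]])
    } else {
      if (p[[k]] <= 0 || p[[k]] > 5)
        stopf("parameter %s must lie in (0, 5], got %g", k, p[[k]])
    }
  }
  structure(p, model = model, reduced = isTRUE(reduced),
            class = "wcst_params")
}

#' Parameter names and constraint kinds per model
#'
#' @param model model id.
#' @return \code{wcst_param_names}: character vector of parameter names in
#'   canonical order; \code{wcst_param_kinds}: named character vector,
#'   \code{"unit"} for parameters constrained to \eqn{[0,1]} and
#'   \code{"five"} for parameters constrained to \eqn{(0,5]}.
#' @export
wcst_param_names <- function(model) {
  switch(model,
    wprl = c("alpha_mb_pos", "alpha_mb_neg", "gamma_mb",
             "alpha_mf_pos", "alpha_mf_neg", "gamma_mf", "tau", "w"),
    prl  = c("alpha_mb_pos", "alpha_mb_neg", "gamma_mb",
             "alpha_mf_pos", "alpha_mf_neg", "gamma_mf", "tau"),
    mbrl = c("alpha_mb_pos", "alpha_mb_neg", "gamma_mb", "tau"),
    au   = c("p_pos", "p_neg", "f", "d"),
    stopf("unknown model id: %s", model))
}

#' @rdname wcst_param_names
#' @export
wcst_param_kinds <- function(model) {
  nm <- wcst_param_names(model)
  kinds <- ifelse(nm %in% c("tau", "f", "d"), "five", "unit")
  names(kinds) <- nm
  kinds
}

#' @export
print.wcst_params <- function(x, digits = 4, ...) {
  cat(sprintf("cWCST model parameters (%s%s)\n", attr(x, "model"),
              if (isTRUE(attr(x, "reduced"))) ", reduced" else ""))
  print(round(unclass(x), digits))
  invisible(x)
}

model_code <- function(model) {
  MODEL_CODES[[match.arg(model, names(MODEL_CODES))]]
}

as_param_vector <- function(params, model = NULL) {
  if (inherits(params, "wcst_params")) {
    if (!is.null(model) && attr(params, "model") != model)
      stopf("parameter vector is for model %s, expected %s",
            attr(params, "model"), model)
    return(unclass(params))
  }
  nm <- wcst_param_names(model)
  if (is.null(names(params))) {
    if (length(params) != length(nm))
      stopf("expected %d parameters for model %s", length(nm), model)
    names(params) <- nm
    return(params)
  }
  params[nm]
}
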