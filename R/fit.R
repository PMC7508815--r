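#' Fit cognitive models of cWCST performance
#'
#' The single fitting front-end. \code{method = "mle"} maximizes each
#' subject's sequence log-likelihood by multi-start quasi-Newton
#' optimization on the unconstrained (probit) scale and returns per-subject
#' point estimates. \code{method = "mcmc"} estimates the full hierarchical
#' Bayesian model (non-centered parameterization; standard-normal priors on
#' group locations and individual effects, half-Cauchy(0, 5) priors on
#' group scales) by adaptive blocked Metropolis-within-Gibbs sampling on
#' the unconstrained space and returns posterior draws with convergence
#' diagnostics.
#'
#' Trial data must be preprocessed: responses matching no category removed
#' (\code{\link{wcst_remove_none}}) and trials in chronological order.
#'
#' @param data a \code{wcst_trials} data frame (one or more subjects).
#' @param model one of \code{"wprl"}, \code{"prl"}, \code{"mbrl"},
#'   \code{"au"}.
#' @param method \code{"mle"} or \code{"mcmc"}.
#' @param reduced reduced AU variant (fixes \code{f = 1},
#'   \code{p_pos = 0.9999}); \code{method = "mle"} only.
#' @param n_restarts number of optimizer starts per subject (mle).
#' @param chains,iter,warmup sampler settings (mcmc); defaults 3 chains of
#'   1,000 iterations with 500 warm-up iterations each.
#' @param seed integer seed (optimizer starts / sampler).
#' @param ... unused.
#' @return for \code{"mle"}, an object of class \code{"wcst_fit"}; for
#'   \code{"mcmc"}, an object of class \code{"wcst_hfit"} (see
#'   \code{\link{summary.wcst_hfit}}).
#' @seealso \code{\link{fit_subject_point}}, \code{\link{wcst_kfold}},
#'   \code{\link{simulate.wcst_fit}}
#' @export
wcst_fit <- function(data, model = c("wprl", "prl", "mbrl", "au"),
                     method = c("mle", "mcmc"), reduced = FALSE,
                     n_restarts = 10, chains = 3, iter = 1000,
                     warmup = 500, seed = NULL, ...) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (method == "mcmc") {
    if (isTRUE(reduced))
      stopf("the reduced AU variant is supported for method = \"mle\" only")
    return(fit_hierarchical(data, model, chains = chains, iter = iter,
                            warmup = warmup, seed = seed))
  }
  subjects <- unique(data$subject_id)
  fits <- vector("list", length(subjects))
  with_seed(seed, {
    for (i in seq_along(subjects)) {
      tr <- data[data$subject_id == subjects[i], , drop = FALSE]
      fits[[i]] <- fit_subject_point(tr, model, n_restarts = n_restarts,
                                     reduced = reduced)
    }
  })
  est <- do.call(rbind, lapply(fits, function(f) f$par))
  rownames(est) <- subjects
  structure(list(model = model, method = "mle", reduced = isTRUE(reduced),
                 estimates = est,
                 logLik = stats::setNames(
                   vapply(fits, function(f) f$logLik, numeric(1)), subjects),
                 n_trials = stats::setNames(
                   vapply(subjects, function(s)
                     sum(data$subject_id == s), numeric(1)), subjects),
                 convergence = vapply(fits, function(f) f$convergence,
                                      numeric(1)),
                 data = data),
            class = "wcst_fit")
}

#' Per-subject maximum-likelihood point estimation
#'
#' Maximizes one subject's sequence log-likelihood over the constrained
#' parameter space via multi-start BFGS on the unconstrained scale (first
#' start at the origin, i.e. all unit-interval parameters at 0.5 and
#' scaled parameters at 2.5; further starts drawn from N(0, 1.5)).
#'
#' @param trials one subject's preprocessed trial data frame.
#' @param model model id.
#' @param n_restarts number of optimizer starts.
#' @param seed optional integer seed for the restart draws.
#' @param reduced reduced AU variant.
#' @return a list with \code{par} (constrained named vector),
#'   \code{logLik}, \code{convergence} (0 = converged) and \code{model}.
#' @export
fit_subject_point <- function(trials, model, n_restarts = 10, seed = NULL,
                              reduced = FALSE) {
  check_fit_trials(trials, model)
  if (!is_count(n_restarts)) stopf("`n_restarts` must be a positive integer")
  code <- model_code(model)
  nm <- wcst_param_names(model)
  free <- nm
  fixed <- numeric(0)
  if (isTRUE(reduced)) {
    if (model != "au") stopf("`reduced` applies to the AU model only")
    fixed <- c(p_pos = 0.9999, f = 1)
    free <- setdiff(nm, names(fixed))
  }
  kinds <- wcst_param_kinds(model)
  to_constrained <- function(x) {
    p <- stats::setNames(numeric(length(nm)), nm)
    p[free] <- ifelse(kinds[free] == "five", 5 * pnorm(x), pnorm(x))
    p[names(fixed)] <- fixed
    p
  }
  negll <- function(x) {
    p <- to_constrained(x)
    -sum(cpp_seq_logp(trials$card_color, trials$card_shape,
                      trials$card_number, trials$response, trials$feedback,
                      p, code))
  }
  with_seed(seed, {
    starts <- c(list(rep(0, length(free))),
                lapply(seq_len(n_restarts - 1L), function(i)
                  rnorm(length(free), sd = 1.5)))
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        optim(s, negll, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best))
      stopf("optimization failed for all %d starts", n_restarts)
    list(par = to_constrained(best$par), logLik = -best$value,
         convergence = best$convergence, model = model,
         reduced = isTRUE(reduced))
  })
}

#' @export
print.wcst_fit <- function(x, digits = 3, ...) {
  cat(sprintf("cWCST %s fit (maximum likelihood), %d subject(s)\n",
              x$model, nrow(x$estimates)))
  cat(sprintf("total log-likelihood: %.2f over %d trials\n",
              sum(x$logLik), sum(x$n_trials)))
  cat("parameter estimates (first subjects):\n")
  print(round(head(x$estimates, 5), digits))
  invisible(x)
}

#' @export
coef.wcst_fit <- function(object, ...) object$estimates

#' @export
logLik.wcst_fit <- function(object, ...) {
  val <- sum(object$logLik)
  attr(val, "df") <- length(wcst_param_names(object$model)) *
    nrow(object$estimates)
  attr(val, "nobs") <- sum(object$n_trials)
  class(val) <- "logLik"
  val
}

#' @export
summary.wcst_fit <- function(object, ...) {
  est <- object$estimates
  tab <- data.frame(
    mean = colMeans(est),
    sd = apply(est, 2, sd),
    min = apply(est, 2, min),
    max = apply(est, 2, max))
  structure(list(model = object$model, n_subjects = nrow(est),
                 parameters = tab, logLik = sum(object$logLik)),
            class = "summary.wcst_fit")
}

#' @export
print.summary.wcst_fit <- function(x, digits = 3, ...) {
  cat(sprintf("cWCST %s fit: %d subject(s), total log-likelihood %.2f\n",
              x$model, x$n_subjects, x$logLik))
  print(round(x$parameters, digits))
  invisible(x)
}

#' Per-trial response probabilities from a fitted model
#'
#' Rebuilds each subject's latent state trajectory from the observed
#' history and returns the model's response probabilities on every trial
#' (probabilities on trial \eqn{t} depend on trials \eqn{1..t-1} only).
#'
#' @param object a \code{wcst_fit}.
#' @param newdata optional trial data frame (defaults to the fitted data);
#'   subjects must have estimates in the fit.
#' @param type \code{"response"} for a T x 4 matrix of key probabilities
#'   per subject, \code{"executed"} for the probability of each executed
#'   response.
#' @param ... unused.
#' @return a named list (one element per subject).
#' @export
predict.wcst_fit <- function(object, newdata = NULL,
                             type = c("response", "executed"), ...) {
  type <- match.arg(type)
  data <- newdata %||% object$data
  subjects <- unique(data$subject_id)
  out <- lapply(subjects, function(s) {
    if (!s %in% rownames(object$estimates))
      stopf("no estimates for subject %s", s)
    tr <- data[data$subject_id == s, , drop = FALSE]
    pm <- cpp_prob_trace(tr$card_color, tr$card_shape, tr$card_number,
                         tr$response, tr$feedback,
                         object$estimates[s, ], model_code(object$model))
    colnames(pm) <- paste0("key", 1:4)
    if (type == "response") pm
    else pm[cbind(seq_len(nrow(pm)), tr$response)]
  })
  names(out) <- subjects
  out
}
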