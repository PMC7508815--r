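#' Agent policy driven by a cognitive model
#'
#' Wraps a parameter vector into a stateful policy for
#' \code{\link{wcst_session}}: the agent samples each response from its
#' model's probabilities and updates its latent state from its own choices
#' and the feedback it receives.
#'
#' @param params a \code{\link{wcst_params}} object.
#' @return a policy function (closure holding the latent state).
#' @export
wcst_agent_policy <- function(params) {
  model <- attr(params, "model")
  state <- if (model == "au") au_init_state() else rl_init_state()
  n_seen <- 0L
  function(card, info) {
    if (!is.null(info$last) && info$trial - 1L > n_seen) {
      l <- info$last
      if (model == "au") {
        sig <- au_feedback_signal(state, l$card, l$response, l$feedback,
                                  params[["f"]])
        state <<- au_update(state, sig, l$feedback, params)
      } else {
        state <<- rl_update(state, l$card, l$response, l$feedback, params)
      }
      n_seen <<- info$trial - 1L
    }
    pr <- if (model == "au") au_response_probs(state, card, params[["d"]])
          else rl_response_probs(state, card, params)
    sample.int(4L, 1L, prob = pr)
  }
}

#' Generative simulation of one agent's session
#'
#' @param params \code{\link{wcst_params}} of the generating model.
#' @param schedule a \code{\link{wcst_schedule}}; a fresh default schedule
#'   is drawn when omitted.
#' @param subject_id subject label.
#' @param seed integer seed (schedule, card draws and agent choices).
#' @return a \code{wcst_trials} data frame with attribute
#'   \code{true_params}.
#' @export
wcst_simulate_agent <- function(params, schedule = NULL,
                                subject_id = "sim1", seed = NULL) {
  with_seed(seed, {
    if (is.null(schedule)) schedule <- wcst_schedule()
    out <- wcst_session(wcst_agent_policy(params), schedule,
                        subject_id = subject_id)
    attr(out, "true_params") <- params
    out
  })
}

## Group-level mean parameters used as cohort defaults. The wP-RL / P-RL /
## MB-RL values follow the reported group-level estimates for this task
## (learning rate after positive feedback 0.995 for "> 0.99", model-free
## learning rate after positive feedback 0.005 for "< 0.01"); the AU
## defaults are field-plausible values chosen by this package.
default_group_means <- function(model) {
  switch(model,
    wprl = c(alpha_mb_pos = 0.995, alpha_mb_neg = 0.60, gamma_mb = 0.31,
             alpha_mf_pos = 0.005, alpha_mf_neg = 0.02, gamma_mf = 0.35,
             tau = 0.09, w = 0.33),
    prl  = c(alpha_mb_pos = 0.995, alpha_mb_neg = 0.60, gamma_mb = 0.31,
             alpha_mf_pos = 0.005, alpha_mf_neg = 0.02, gamma_mf = 0.35,
             tau = 0.09),
    mbrl = c(alpha_mb_pos = 0.995, alpha_mb_neg = 0.60, gamma_mb = 0.31,
             tau = 0.09),
    au   = c(p_pos = 0.9, p_neg = 0.3, f = 1, d = 2),
    stopf("unknown model id: %s", model))
}

#' Synthetic cohort of model-driven agents
#'
#' Generates N independent agents whose individual parameters scatter
#' around group-level means: the means are mapped to the unconstrained
#' scale, a normal deviate with the given dispersion is added per subject
#' and parameter, and the result is constrained back. Each agent plays an
#' independent session on its own schedule.
#'
#' @param n number of agents.
#' @param model generating model id.
#' @param means named vector of constrained group-level parameter means
#'   (defaults per model, see Details in the package vignette).
#' @param dispersion between-subject SD on the unconstrained scale
#'   (default 0.5; 0 gives identical agents).
#' @param n_switches,max_trials session configuration.
#' @param seed integer master seed (the whole cohort is reproducible from
#'   it).
#' @param subject_prefix prefix for subject ids.
#' @return an object of class \code{"wcst_cohort"}: list with
#'   \code{trials} (all sessions row-bound) and \code{truth} (one row per
#'   subject: generating parameters, session length, completed switches).
#' @export
wcst_cohort <- function(n, model = c("wprl", "prl", "mbrl", "au"),
                        means = NULL, dispersion = 0.5, n_switches = 41,
                        max_trials = 250, seed = NULL,
                        subject_prefix = "sim") {
  model <- match.arg(model)
  if (!is_count(n)) stopf("`n` must be a positive integer")
  if (dispersion < 0) stopf("`dispersion` must be >= 0")
  means <- means %||% default_group_means(model)
  mu <- unconstrain_vector(means, model)
  nm <- wcst_param_names(model)
  with_seed(seed, {
    sessions <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        theta <- constrain_vector(mu + rnorm(length(nm), 0, dispersion),
                                  model)
        ok <- tryCatch({
          wcst_params(model, theta); TRUE
        }, error = function(e) FALSE)
        if (ok) break
      }
      params <- wcst_params(model, theta)
      id <- sprintf("%s%03d", subject_prefix, i)
      schedule <- wcst_schedule(n_switches = n_switches,
                                max_trials = max_trials)
      tr <- wcst_session(wcst_agent_policy(params), schedule,
                         subject_id = id)
      sessions[[i]] <- tr
      truth[[i]] <- data.frame(
        subject_id = id, t(unclass(params)),
        n_trials = nrow(tr),
        completed_switches = attr(tr, "completed_switches"),
        stringsAsFactors = FALSE)
    }
    structure(list(trials = as_wcst_trials(do.call(rbind, sessions)),
                   truth = do.call(rbind, truth), model = model,
                   means = means, dispersion = dispersion, seed = seed),
              class = "wcst_cohort")
  })
}

#' @export
print.wcst_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cWCST cohort: %d %s agents, %d trials (mean %.1f per agent)\n",
    nrow(x$truth), x$model, nrow(x$trials), mean(x$truth$n_trials)))
  invisible(x)
}

#' One-trial-ahead (post-hoc absolute fit) simulation
#'
#' For each iteration one parameter vector is used (a posterior draw, or a
#' fixed point estimate); for every trial \eqn{t} the latent state is
#' rebuilt from the subject's \emph{observed} responses and feedback on
#' trials \eqn{1..t-1} and a response is sampled from the model's
#' probabilities on trial \eqn{t}. Simulated responses on different trials
#' are therefore conditionally independent given the observed history.
#'
#' @param trials one subject's observed, preprocessed trials.
#' @param params parameter source: a \code{\link{wcst_params}} object
#'   (point parameters, replicated across iterations), a numeric matrix of
#'   per-iteration parameter vectors, or a \code{wcst_hfit} (the subject's
#'   individual posterior draws are resampled).
#' @param model model id; inferred from \code{params} when possible.
#' @param n_iter number of iterations (default 1,000).
#' @param seed integer seed.
#' @return an object of class \code{"wcst_onestep"}: list with
#'   \code{responses} (n_iter x T matrix of simulated key presses),
#'   \code{observed} (the input trials) and \code{model}.
#' @export
simulate_one_step_ahead <- function(trials, params, model = NULL,
                                    n_iter = 1000, seed = NULL) {
  if (!is_count(n_iter)) stopf("`n_iter` must be a positive integer")
  if (inherits(params, "wcst_params")) {
    model <- attr(params, "model")
    pm <- matrix(unclass(params), n_iter, length(params), byrow = TRUE)
  } else if (inherits(params, "wcst_hfit")) {
    model <- params$model
    s <- trials$subject_id[1L]
    if (!s %in% params$subjects)
      stopf("subject %s not in the posterior fit", s)
    th <- params$draws$theta[, , match(s, params$subjects), , drop = FALSE]
    th <- matrix(th, ncol = dim(params$draws$theta)[4L])
    pm <- with_seed(seed,
      th[sample.int(nrow(th), n_iter, replace = TRUE), , drop = FALSE])
    seed <- if (is.null(seed)) NULL else seed + 1L
  } else if (is.matrix(params)) {
    if (is.null(model)) stopf("`model` is required with a parameter matrix")
    pm <- params[rep_len(seq_len(nrow(params)), n_iter), , drop = FALSE]
  } else stopf("unsupported `params`")
  check_fit_trials(trials, model)
  resp <- with_seed(seed,
    cpp_one_step_ahead(trials$card_color, trials$card_shape,
                       trials$card_number, trials$response,
                       trials$feedback, pm, model_code(model)))
  structure(list(responses = resp, observed = trials, model = model,
                 n_iter = n_iter),
            class = "wcst_onestep")
}

#' @export
print.wcst_onestep <- function(x, ...) {
  cat(sprintf(
    "One-trial-ahead simulation: %d iterations x %d trials (%s model)\n",
    nrow(x$responses), ncol(x$responses), x$model))
  invisible(x)
}

#' One-trial-ahead posterior-predictive simulation from a fit
#'
#' \code{simulate()} on a fitted object runs
#' \code{\link{simulate_one_step_ahead}} for each requested subject with
#' that subject's point estimate (\code{wcst_fit}) or posterior draws
#' (\code{wcst_hfit}).
#'
#' @param object a fitted object.
#' @param nsim iterations per subject.
#' @param seed integer seed.
#' @param subjects subset of subject ids (default: all fitted subjects).
#' @param ... unused.
#' @return named list of \code{wcst_onestep} objects.
#' @export
simulate.wcst_fit <- function(object, nsim = 1000, seed = NULL,
                              subjects = NULL, ...) {
  subjects <- subjects %||% rownames(object$estimates)
  out <- lapply(seq_along(subjects), function(i) {
    s <- subjects[i]
    tr <- object$data[object$data$subject_id == s, , drop = FALSE]
    p <- wcst_params(object$model, object$estimates[s, ])
    simulate_one_step_ahead(tr, p, n_iter = nsim,
                            seed = if (is.null(seed)) NULL else seed + i)
  })
  names(out) <- subjects
  out
}

#' @rdname simulate.wcst_fit
#' @export
simulate.wcst_hfit <- function(object, nsim = 1000, seed = NULL,
                               subjects = NULL, ...) {
  subjects <- subjects %||% object$subjects
  out <- lapply(seq_along(subjects), function(i) {
    s <- subjects[i]
    tr <- object$data[object$data$subject_id == s, , drop = FALSE]
    simulate_one_step_ahead(tr, object, n_iter = nsim,
                            seed = if (is.null(seed)) NULL else seed + i)
  })
  names(out) <- subjects
  out
}
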