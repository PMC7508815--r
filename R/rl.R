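#' Reinforcement-learning latent state
#'
#' The parallel RL models carry two sets of feedback expectations: a
#' 3-vector \code{q_c} over sorting categories (model-based level) and a
#' 4-vector \code{q_mf} over responses (model-free level). Both are
#' initialized at zero.
#'
#' @return a list with elements \code{q_c} (length 3, named by category)
#'   and \code{q_mf} (length 4).
#' @export
rl_init_state <- function() {
  list(q_c = stats::setNames(c(0, 0, 0), WCST_CATEGORIES),
       q_mf = c(0, 0, 0, 0))
}

#' Model-based feedback expectations of the four responses
#'
#' Each response inherits the category expectation of the unique category
#' on which the card matches that key; the card's unmatched key — which is
#' certain to yield negative feedback — is assigned a fixed expectation of
#' -1.
#'
#' @param state an \code{\link{rl_init_state}} state.
#' @param card a deck-valid card (see \code{\link{wcst_applied_category}}).
#' @return numeric 4-vector of model-based response values.
#' @export
rl_mb_values <- function(state, card) {
  card <- as_card(card)
  vapply(1:4, function(v) {
    d <- which(card == v)
    if (length(d) == 0L) -1 else unname(state$q_c[d])
  }, numeric(1))
}

#' Response probabilities of the RL models
#'
#' Model-based and model-free expectations are integrated — weighted
#' (\code{wprl}: \eqn{w Q_{MB} + (1-w) Q_{MF}}), unweighted (\code{prl}:
#' \eqn{Q_{MB} + Q_{MF}}) or model-based alone (\code{mbrl}) — and passed
#' through a softmax with temperature \code{tau}.
#'
#' @inheritParams rl_mb_values
#' @param params a \code{\link{wcst_params}} object for an RL model.
#' @return probability 4-vector (sums to 1; all entries strictly positive).
#' @export
rl_response_probs <- function(state, card, params) {
  model <- attr(params, "model")
  if (!model %in% c("wprl", "prl", "mbrl"))
    stopf("`params` must belong to an RL model")
  p <- as_param_vector(params, model)
  if (p[["tau"]] <= 0) stopf("temperature tau must be positive")
  qmb <- rl_mb_values(state, card)
  qsum <- switch(model,
    wprl = p[["w"]] * qmb + (1 - p[["w"]]) * state$q_mf,
    prl  = qmb + state$q_mf,
    mbrl = qmb)
  softmax(qsum / p[["tau"]])
}

#' Delta-rule state update of the RL models
#'
#' Both expectation vectors first decay multiplicatively by their inertia
#' parameter. The applied category's expectation is then moved toward the
#' feedback by a prediction error scaled by the feedback-sign-specific
#' learning rate; for \code{wprl}/\code{prl} the executed response's
#' model-free expectation is updated analogously. If the response matched
#' no category, no category-level prediction error exists; by default the
#' category expectations only decay (\code{mb_none = "decay"}), while the
#' model-free update proceeds normally. (Such trials are removed before
#' fitting; this rule matters for generative simulation only.)
#'
#' @inheritParams rl_response_probs
#' @param response executed key index in 1..4.
#' @param feedback \code{+1} or \code{-1}.
#' @param mb_none handling of the category level when no category was
#'   applied: \code{"decay"} (default) or \code{"freeze"} (no decay).
#' @return the updated state.
#' @examples
#' s <- rl_init_state(); s$q_c[1] <- 0.8
#' p <- wcst_params("mbrl", alpha_mb_pos = 1, alpha_mb_neg = 0.6,
#'                  gamma_mb = 0.5, tau = 1)
#' rl_update(s, c(1, 2, 3), 1, -1, p)$q_c[1]  # -0.44
#' @export
rl_update <- function(state, card, response, feedback, params,
                      mb_none = c("decay", "freeze")) {
  mb_none <- match.arg(mb_none)
  model <- attr(params, "model")
  if (!model %in% c("wprl", "prl", "mbrl"))
    stopf("`params` must belong to an RL model")
  if (!feedback %in% c(-1, 1)) stopf("`feedback` must be +1 or -1")
  p <- as_param_vector(params, model)
  card <- as_card(card)
  u <- which(card == response)
  if (length(u) > 0L || mb_none == "decay")
    state$q_c <- p[["gamma_mb"]] * state$q_c
  if (length(u) > 0L) {
    delta <- feedback - state$q_c[[u]]
    a <- if (feedback > 0) p[["alpha_mb_pos"]] else p[["alpha_mb_neg"]]
    state$q_c[[u]] <- state$q_c[[u]] + a * delta
  }
  if (model != "mbrl") {
    state$q_mf <- p[["gamma_mf"]] * state$q_mf
    delta <- feedback - state$q_mf[[response]]
    a <- if (feedback > 0) p[["alpha_mf_pos"]] else p[["alpha_mf_neg"]]
    state$q_mf[[response]] <- state$q_mf[[response]] + a * delta
  }
  state
}

## shared validation for sequence likelihoods
check_fit_trials <- function(trials, model_label) {
  stopifnot(is.data.frame(trials))
  need <- c("subject_id", "trial_index", "card_color", "card_shape",
            "card_number", "response", "feedback")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stopf("trial data lack column(s): %s", paste(missing, collapse = ", "))
  if (nrow(trials) == 0L) stopf("empty trial sequence")
  if (length(unique(trials$subject_id)) > 1L)
    stopf("sequence likelihoods take one subject at a time")
  if (is.unsorted(trials$trial_index, strictly = TRUE))
    stopf("trials must be in strictly increasing chronological order")
  applied <- applied_of(trials)
  if (any(applied == "none"))
    stopf(paste0("%s likelihood: trial(s) %s have responses matching no ",
                 "category; remove them first (see wcst_remove_none)"),
          model_label,
          paste(head(trials$trial_index[applied == "none"], 5),
                collapse = ", "))
  invisible(trials)
}

applied_of <- function(trials) {
  d1 <- trials$card_color == trials$response
  d2 <- trials$card_shape == trials$response
  d3 <- trials$card_number == trials$response
  ifelse(d1, "color", ifelse(d2, "shape", ifelse(d3, "number", "none")))
}

## pure-R reference walk, shared by rl/au sequence likelihoods
seq_loglik_r <- function(trials, params) {
  model <- attr(params, "model")
  n <- nrow(trials)
  lp <- numeric(n)
  if (model == "au") {
    state <- au_init_state()
    for (t in seq_len(n)) {
      card <- c(trials$card_color[t], trials$card_shape[t],
                trials$card_number[t])
      pr <- au_response_probs(state, card, params[["d"]])
      lp[t] <- log(pr[[trials$response[t]]])
      sig <- au_feedback_signal(state, card, trials$response[t],
                                trials$feedback[t], params[["f"]])
      state <- au_update(state, sig, trials$feedback[t], params)
    }
  } else {
    state <- rl_init_state()
    for (t in seq_len(n)) {
      card <- c(trials$card_color[t], trials$card_shape[t],
                trials$card_number[t])
      pr <- rl_response_probs(state, card, params)
      lp[t] <- log(pr[[trials$response[t]]])
      state <- rl_update(state, card, trials$response[t],
                         trials$feedback[t], params)
    }
  }
  lp
}

#' Sequence log-likelihood of the RL models
#'
#' Walks one subject's preprocessed trial sequence (chronological,
#' none-category responses removed), accumulating the log probability of
#' each executed response and updating the latent state with the executed
#' response and received feedback.
#'
#' @param trials one subject's trial data frame (see
#'   \code{\link{wcst_session}} for the column layout).
#' @param params RL \code{\link{wcst_params}}.
#' @param engine \code{"cpp"} (default, compiled) or \code{"r"} (reference
#'   implementation built from the step functions).
#' @return a list with \code{total} and \code{per_trial} log-probabilities.
#' @export
rl_sequence_loglik <- function(trials, params, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  model <- attr(params, "model")
  if (!model %in% c("wprl", "prl", "mbrl"))
    stopf("`params` must belong to an RL model")
  check_fit_trials(trials, "RL")
  lp <- if (engine == "cpp") {
    cpp_seq_logp(trials$card_color, trials$card_shape, trials$card_number,
                 trials$response, trials$feedback,
                 as_param_vector(params, model), model_code(model))
  } else seq_loglik_r(trials, params)
  list(total = sum(lp), per_trial = lp)
}
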