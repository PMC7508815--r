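#' Attentional-updating latent state
#'
#' The AU model carries a 3-vector of attentional category prioritizations
#' on the unit simplex, initialized at 1/3 each.
#'
#' @return a list with element \code{a} (length 3, named by category).
#' @export
au_init_state <- function() {
  list(a = stats::setNames(rep(1 / 3, 3), WCST_CATEGORIES))
}

AU_FLOOR <- 1e-12 # attention floor before exponentiation (implementation
                  # tolerance, not model content)

#' AU feedback signal
#'
#' After positive feedback the signal concentrates on the categories
#' matched by the chosen key (one-hot at the applied category for
#' deck-valid cards); after negative feedback it redistributes attention
#' over the unmatched categories. In both cases the current attention,
#' raised to the attentional focus \code{f}, weights the redistribution and
#' the signal is normalized to the simplex.
#'
#' @param state an \code{\link{au_init_state}} state.
#' @param card deck-valid card.
#' @param response executed key index (must match a category).
#' @param feedback \code{+1} or \code{-1}.
#' @param f attentional focus in (0, 5).
#' @return a 3-vector on the simplex.
#' @export
au_feedback_signal <- function(state, card, response, feedback, f) {
  card <- as_card(card)
  u <- which(card == response)
  if (length(u) == 0L)
    stopf("AU feedback signal undefined for a response matching no category")
  af <- pmax(state$a, AU_FLOOR)^f
  m <- as.numeric(seq_len(3L) == u)
  w <- if (feedback > 0) m * af else (1 - m) * af
  stats::setNames(w / sum(w), WCST_CATEGORIES)
}

#' AU attention update
#'
#' Convex combination of the previous attention vector and the feedback
#' signal, with mixing ratio \code{p_pos} after positive and \code{p_neg}
#' after negative feedback.
#'
#' @inheritParams au_feedback_signal
#' @param signal feedback signal (3-vector on the simplex).
#' @param params AU \code{\link{wcst_params}}.
#' @return the updated state (attention stays on the simplex).
#' @export
au_update <- function(state, signal, feedback, params) {
  p <- as_param_vector(params, "au")
  rate <- if (feedback > 0) p[["p_pos"]] else p[["p_neg"]]
  state$a <- (1 - rate) * state$a + rate * signal
  state
}

#' AU response probabilities
#'
#' Each category-matched key receives probability proportional to the
#' attention of its category raised to the decision consistency \code{d};
#' the card's unmatched key receives probability exactly 0.
#'
#' @inheritParams au_feedback_signal
#' @param d decision consistency in (0, 5).
#' @return probability 4-vector (sums to 1; exactly one entry is 0).
#' @export
au_response_probs <- function(state, card, d) {
  card <- as_card(card)
  ad <- pmax(state$a, AU_FLOOR)^d
  pr <- vapply(1:4, function(v) {
    dim <- which(card == v)
    if (length(dim) == 0L) 0 else unname(ad[dim])
  }, numeric(1))
  pr / sum(pr)
}

#' Sequence log-likelihood of the AU model
#'
#' As \code{\link{rl_sequence_loglik}}, for the attentional-updating
#' benchmark. The AU model assigns probability zero to responses matching
#' no category, so such trials must be removed beforehand (they are named
#' in the error otherwise).
#'
#' @inheritParams rl_sequence_loglik
#' @param params AU \code{\link{wcst_params}}.
#' @return a list with \code{total} and \code{per_trial} log-probabilities.
#' @export
au_sequence_loglik <- function(trials, params, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!identical(attr(params, "model"), "au"))
    stopf("`params` must belong to the AU model")
  check_fit_trials(trials, "AU")
  lp <- if (engine == "cpp") {
    cpp_seq_logp(trials$card_color, trials$card_shape, trials$card_number,
                 trials$response, trials$feedback,
                 as_param_vector(params, "au"), 4L)
  } else seq_loglik_r(trials, params)
  list(total = sum(lp), per_trial = lp)
}
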