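# shared fixtures, built in code

table4_wprl <- function() {
  wcst_params("wprl", alpha_mb_pos = 0.995, alpha_mb_neg = 0.60,
              gamma_mb = 0.31, alpha_mf_pos = 0.005, alpha_mf_neg = 0.02,
              gamma_mf = 0.35, tau = 0.09, w = 0.33)
}

default_prl <- function() {
  wcst_params("prl", alpha_mb_pos = 0.995, alpha_mb_neg = 0.60,
              gamma_mb = 0.31, alpha_mf_pos = 0.005, alpha_mf_neg = 0.02,
              gamma_mf = 0.35, tau = 0.09)
}

default_mbrl <- function(tau = 0.09) {
  wcst_params("mbrl", alpha_mb_pos = 0.995, alpha_mb_neg = 0.60,
              gamma_mb = 0.31, tau = tau)
}

default_au <- function() {
  wcst_params("au", p_pos = 0.9, p_neg = 0.3, f = 1, d = 2)
}

## a short session from a random policy (none-category responses removed),
## useful for likelihood identities that must hold on arbitrary data
random_trials <- function(seed, n_switches = 8, keep_none = FALSE) {
  tr <- wcst_session(wcst_policy_random(),
                     wcst_schedule(n_switches = n_switches, seed = seed),
                     seed = seed + 1000L)
  if (keep_none) tr else wcst_remove_none(tr)
}

## hand-build a trial data frame from parallel vectors
make_trials <- function(cards, responses, feedbacks, targets = NULL,
                        subject = "t1", start_index = 1L) {
  cards <- do.call(rbind, cards)
  n <- nrow(cards)
  applied <- vapply(seq_len(n), function(t)
    wcst_applied_category(cards[t, ], responses[t]), character(1))
  targets <- targets %||% ifelse(feedbacks > 0, applied,
                                 vapply(applied, function(a)
                                   setdiff(c("color", "shape", "number"),
                                           a)[1L], character(1)))
  data.frame(subject_id = subject,
             trial_index = seq.int(start_index, length.out = n),
             card_color = cards[, 1L], card_shape = cards[, 2L],
             card_number = cards[, 3L], response = as.integer(responses),
             feedback = as.integer(feedbacks), target_category = targets,
             applied_category = applied, stringsAsFactors = FALSE)
}

## apply a key-relabeling permutation to cards and responses
relabel_keys <- function(trials, perm) {
  out <- trials
  out$card_color <- perm[trials$card_color]
  out$card_shape <- perm[trials$card_shape]
  out$card_number <- perm[trials$card_number]
  out$response <- perm[trials$response]
  out
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

expect_simplex <- function(x, tol = 1e-12) {
  expect_true(all(x >= 0))
  expect_lt(abs(sum(x) - 1), tol)
}
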