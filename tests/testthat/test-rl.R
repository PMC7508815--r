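test_that("the initial RL state is zero and yields uniform category-mapped choice", {
  st <- rl_init_state()
  expect_equal(unname(st$q_c), c(0, 0, 0))
  expect_equal(st$q_mf, c(0, 0, 0, 0))
  ## at the zero state the three category-mapped keys share one probability
  ## and only the unmatched key (model-based value -1) differs
  pr <- rl_response_probs(st, c(2, 3, 4), default_mbrl(tau = 1))
  expect_equal(pr[2], pr[3])
  expect_equal(pr[3], pr[4])
  expect_lt(pr[1], pr[2])
  expect_equal(pr, softmax(c(-1, 0, 0, 0)))
})

test_that("model-based response values map categories to keys with -1 at the unmatched key", {
  st <- rl_init_state()
  st$q_c <- c(color = 0.5, shape = -0.2, number = 0.1)
  expect_equal(rl_mb_values(st, c(2, 3, 4)), c(-1, 0.5, -0.2, 0.1))
  expect_equal(rl_mb_values(rl_init_state(), c(3, 1, 2)), c(0, 0, 0, -1))
  ## permuting the card permutes the values
  expect_equal(rl_mb_values(st, c(3, 2, 4)), c(-1, -0.2, 0.5, 0.1))
})

test_that("softmax choice follows the integrated expectations", {
  st <- rl_init_state()
  st$q_c <- c(color = 1, shape = 0, number = 0)
  ## card (1,2,3): key v applies category v for v in 1..3; key 4 unmatched
  pr <- rl_response_probs(st, c(1, 2, 3), default_mbrl(tau = 1))
  expect_equal(pr, exp(c(1, 0, 0, -1)) / sum(exp(c(1, 0, 0, -1))),
               tolerance = 1e-12)
  ## lowering the temperature makes the best response strictly more likely
  pr_cold <- rl_response_probs(st, c(1, 2, 3), default_mbrl(tau = 0.5))
  expect_gt(max(pr_cold), max(pr))
  expect_error(wcst_params("mbrl", alpha_mb_pos = 1, alpha_mb_neg = 1,
                           gamma_mb = 1, tau = 0), "tau")
})

test_that("the delta-rule update reproduces hand-computed values", {
  p <- wcst_params("mbrl", alpha_mb_pos = 1, alpha_mb_neg = 0.6,
                   gamma_mb = 0.5, tau = 1)
  st <- rl_init_state()
  st$q_c[["color"]] <- 0.8
  ## decay 0.8 -> 0.4; delta = -1.4; 0.4 + 0.6 * (-1.4) = -0.44
  up <- rl_update(st, c(1, 2, 3), 1, -1, p)
  expect_equal(unname(up$q_c[["color"]]), -0.44, tolerance = 1e-12)
  ## full positive update from zero reaches exactly 1
  p2 <- wcst_params("mbrl", alpha_mb_pos = 1, alpha_mb_neg = 1,
                    gamma_mb = 1, tau = 1)
  up2 <- rl_update(rl_init_state(), c(1, 2, 3), 1, 1, p2)
  expect_equal(unname(up2$q_c), c(1, 0, 0))
  ## zero learning rate leaves the response expectation untouched
  p3 <- wcst_params("prl", alpha_mb_pos = 1, alpha_mb_neg = 1, gamma_mb = 1,
                    alpha_mf_pos = 0, alpha_mf_neg = 0.5, gamma_mf = 1,
                    tau = 1)
  st3 <- rl_init_state(); st3$q_mf[2] <- 0.5
  expect_equal(rl_update(st3, c(2, 3, 4), 2, 1, p3)$q_mf[2], 0.5)
  ## a response matching no category: categories decay only
  st4 <- rl_init_state(); st4$q_c[["color"]] <- 0.8
  up4 <- rl_update(st4, c(2, 3, 4), 1, -1, p) # key 1 unmatched
  expect_equal(unname(up4$q_c[["color"]]), 0.4)
})

test_that("probabilities stay on the simplex and expectations stay in [-1, 1]", {
  set.seed(31)
  for (rep in 1:5) {
    model <- sample(c("wprl", "prl", "mbrl"), 1)
    kinds <- wcst_param_kinds(model)
    vals <- ifelse(kinds == "five", runif(length(kinds), 0.05, 5),
                   runif(length(kinds)))
    names(vals) <- names(kinds)
    p <- wcst_params(model, vals)
    st <- rl_init_state()
    tr <- random_trials(seed = 100 + rep, keep_none = TRUE)
    for (t in seq_len(nrow(tr))) {
      card <- c(tr$card_color[t], tr$card_shape[t], tr$card_number[t])
      expect_simplex(rl_response_probs(st, card, p))
      st <- rl_update(st, card, tr$response[t], tr$feedback[t], p)
      expect_true(all(abs(st$q_c) <= 1 + 1e-12))
      expect_true(all(abs(st$q_mf) <= 1 + 1e-12))
    }
  }
})

test_that("sequence log-likelihood matches a one-step hand evaluation", {
  p <- default_prl()
  tr <- make_trials(list(c(2, 3, 4)), responses = 3, feedbacks = -1)
  out <- rl_sequence_loglik(tr, p)
  qsum <- c(-1, 0, 0, 0) # model-based values at the zero state, key 1 unmatched
  expect_equal(out$total, log(softmax(qsum / 0.09)[3]), tolerance = 1e-12)
  expect_equal(sum(out$per_trial), out$total, tolerance = 1e-10)
})

test_that("model-equivalence identities hold on arbitrary sequences", {
  mb <- c(alpha_mb_pos = 0.9, alpha_mb_neg = 0.4, gamma_mb = 0.7)
  mf <- c(alpha_mf_pos = 0.2, alpha_mf_neg = 0.3, gamma_mf = 0.5)
  for (s in 1:10) {
    tr <- random_trials(seed = 200 + s)
    ## wP-RL with w = 1 collapses onto MB-RL
    l1 <- rl_sequence_loglik(tr, wcst_params("wprl", c(mb, mf, tau = 0.4,
                                                       w = 1)))$total
    l2 <- rl_sequence_loglik(tr, wcst_params("mbrl", c(mb, tau = 0.4)))$total
    expect_equal(l1, l2, tolerance = 1e-12)
    ## wP-RL at w = 0.5 with halved temperature equals P-RL
    l3 <- rl_sequence_loglik(tr, wcst_params("wprl", c(mb, mf, tau = 0.2,
                                                       w = 0.5)))$total
    l4 <- rl_sequence_loglik(tr, wcst_params("prl", c(mb, mf,
                                                      tau = 0.4)))$total
    expect_equal(l3, l4, tolerance = 1e-12)
    ## with model-free learning silenced, wP-RL is MB-RL at temperature tau/w
    l5 <- rl_sequence_loglik(tr, wcst_params("wprl",
      c(mb, alpha_mf_pos = 0, alpha_mf_neg = 0, gamma_mf = 0.8,
        tau = 0.28, w = 0.7)))$total
    l6 <- rl_sequence_loglik(tr, wcst_params("mbrl", c(mb,
                                                       tau = 0.4)))$total
    expect_equal(l5, l6, tolerance = 1e-12)
  }
})

test_that("log-likelihood is invariant to a consistent key relabeling", {
  p <- table4_wprl()
  perm <- c(3L, 1L, 4L, 2L)
  for (s in 1:5) {
    tr <- random_trials(seed = 300 + s)
    expect_equal(rl_sequence_loglik(relabel_keys(tr, perm), p)$total,
                 rl_sequence_loglik(tr, p)$total, tolerance = 1e-10)
  }
})

test_that("compiled and reference likelihood engines agree", {
  for (s in 1:5) {
    tr <- random_trials(seed = 400 + s)
    p <- table4_wprl()
    a <- rl_sequence_loglik(tr, p, engine = "cpp")
    b <- rl_sequence_loglik(tr, p, engine = "r")
    expect_equal(a$per_trial, b$per_trial, tolerance = 1e-12)
  }
})

test_that("ill-formed sequences are rejected", {
  p <- default_mbrl()
  tr <- random_trials(seed = 21)
  bad <- tr[rev(seq_len(nrow(tr))), ]
  expect_error(rl_sequence_loglik(bad, p), "chronological")
  two <- rbind(tr, transform(tr, subject_id = "other"))
  expect_error(rl_sequence_loglik(two, p), "one subject")
  with_none <- random_trials(seed = 22, keep_none = TRUE)
  if (any(cwcst:::applied_of(with_none) == "none"))
    expect_error(rl_sequence_loglik(with_none, p), "no category")
})
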