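test_that("none-category responses are removed with a report, idempotently", {
  tr <- make_trials(list(c(2, 3, 4), c(3, 4, 1), c(1, 2, 3)),
                    responses = c(2, 2, 3), feedbacks = c(1, -1, 1))
  ## trial 2: key 2 is unmatched on card (3,4,1)
  out <- wcst_remove_none(tr)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "removal_report")$trial_index, 2L)
  expect_equal(attr(out, "removal_fraction"), 1 / 3)
  again <- wcst_remove_none(out)
  expect_equal(attr(again, "removal_fraction"), 0)
  expect_equal(again$trial_index, out$trial_index)
  expect_equal(again$response, out$response)
})

test_that("trial classification reproduces the hand-traced demand rules", {
  ## negative feedback on color (key 2 on card (2,3,4)); on card (2,1,3)
  ## key 2 again applies color, so committing the perseveration repeats
  ## the key: demanded alternation
  tr <- make_trials(list(c(2, 3, 4), c(2, 1, 3)), responses = c(2, 2),
                    feedbacks = c(-1, -1))
  cls <- wcst_classify(tr)
  expect_equal(cls$error_type[2], "perseveration")
  expect_equal(cls$demand[2], "alternation")
  expect_true(cls$error[2]) # key 2 applies color again
  ## same history, but on card (1,2,4) key 2 applies shape: the error
  ## response now alternates keys, so a repetition is demanded
  tr2 <- make_trials(list(c(2, 3, 4), c(1, 2, 4)), responses = c(2, 4),
                     feedbacks = c(-1, -1))
  cls2 <- wcst_classify(tr2)
  expect_equal(cls2$error_type[2], "perseveration")
  expect_equal(cls2$demand[2], "repetition")
  expect_false(cls2$error[2]) # key 4 on (1,2,4) applies number: a switch
  ## positive feedback on color; key 2 still maps to color: repeating the
  ## category repeats the key (demanded repetition); switching is set-loss
  tr3 <- make_trials(list(c(2, 3, 4), c(2, 1, 3)), responses = c(2, 1),
                     feedbacks = c(1, -1))
  cls3 <- wcst_classify(tr3)
  expect_equal(cls3$error_type[2], "set_loss")
  expect_equal(cls3$demand[2], "repetition")
  expect_true(cls3$error[2]) # key 1 applies shape on (2,1,3)
  ## first trials and trials after a gap are unscored
  expect_false(cls$scored[1])
  gap <- tr
  gap$trial_index[2] <- 3L
  expect_false(wcst_classify(gap)$scored[2])
})

test_that("demand goes unclassified when the previous key matches nothing", {
  ## prev key 4 (number on (2,3,4)); on card (1,2,3) key 4 is unmatched
  tr <- make_trials(list(c(2, 3, 4), c(1, 2, 3)), responses = c(4, 1),
                    feedbacks = c(-1, -1))
  cls <- wcst_classify(tr)
  expect_equal(cls$demand[2], "unclassified")
  expect_equal(cls$error_type[2], "perseveration")
})

test_that("conditional error tables divide errors by opportunities", {
  ## ten alternation-demand perseveration opportunities, two committed:
  ## key 2 applies color on both consecutive cards; the probe response
  ## either repeats color (error) or switches to shape
  cards <- list(); responses <- integer(0); feedbacks <- integer(0)
  for (i in 1:10) {
    cards <- c(cards, list(c(2, 3, 4), c(2, 1, 3)))
    responses <- c(responses, 2L, if (i <= 2) 2L else 1L)
    feedbacks <- c(feedbacks, -1L, -1L)
  }
  ## separate the 10 pairs so only within-pair transitions are scored
  tr <- do.call(rbind, lapply(1:10, function(i)
    make_trials(cards[(2 * i - 1):(2 * i)],
                responses[(2 * i - 1):(2 * i)],
                feedbacks[(2 * i - 1):(2 * i)],
                start_index = 10L * i)))
  tab <- wcst_error_table(tr)
  cell <- tab[tab$error_type == "perseveration" &
                tab$demand == "alternation", ]
  expect_equal(cell$opportunities, 10L)
  expect_equal(cell$errors, 2L)
  expect_equal(cell$probability, 0.2)
  ## empty cells are missing, not zero
  expect_true(is.na(tab$probability[tab$error_type == "set_loss" &
                                      tab$demand == "repetition"]))
})

test_that("a win-stay/lose-shift performer commits no scored errors", {
  ## always repeat the applied category after positive feedback and switch
  ## (cyclically) after negative feedback: never perseverates, never loses
  ## the set
  cats <- c("color", "shape", "number")
  wsls <- function(card, info) {
    if (is.null(info$last)) return(card[[1L]]) # apply color first
    prev <- info$last$applied
    nxt <- if (info$last$feedback > 0) prev
           else cats[match(prev, cats) %% 3L + 1L]
    card[[match(nxt, cats)]]
  }
  tr <- wcst_remove_none(
    wcst_session(wsls, wcst_schedule(seed = 31), seed = 32))
  tab <- wcst_error_table(tr)
  expect_true(all(tab$errors == 0))
})

test_that("error counting agrees with an independent re-scan and key relabeling", {
  brute_count <- function(tr) {
    ap <- cwcst:::applied_of(tr)
    out <- c(pr = 0, po = 0, sr = 0, so = 0, p_rep = 0, p_alt = 0)
    for (t in seq_len(nrow(tr))[-1]) {
      if (tr$trial_index[t] != tr$trial_index[t - 1] + 1) next
      prev_cat_of_key <- wcst_applied_category(
        c(tr$card_color[t], tr$card_shape[t], tr$card_number[t]),
        tr$response[t - 1])
      if (tr$feedback[t - 1] < 0) {
        dm <- if (prev_cat_of_key == "none") NA
              else if (prev_cat_of_key == ap[t - 1]) "alt" else "rep"
        if (is.na(dm)) next
        if (dm == "alt") { out["po"] <- out["po"] + 1
          if (ap[t] == ap[t - 1]) out["p_alt"] <- out["p_alt"] + 1
        } else { out["pr"] <- out["pr"] + 1
          if (ap[t] == ap[t - 1]) out["p_rep"] <- out["p_rep"] + 1 }
      }
    }
    out
  }
  p <- table4_wprl()
  for (s in 1:3) {
    tr <- wcst_remove_none(wcst_simulate_agent(p, seed = 40 + s))
    tab <- wcst_error_table(tr)
    ref <- brute_count(tr)
    prow <- function(dm) tab[tab$error_type == "perseveration" &
                               tab$demand == dm, ]
    expect_equal(prow("repetition")$opportunities, unname(ref["pr"]))
    expect_equal(prow("alternation")$opportunities, unname(ref["po"]))
    expect_equal(prow("repetition")$errors, unname(ref["p_rep"]))
    expect_equal(prow("alternation")$errors, unname(ref["p_alt"]))
    expect_true(all(tab$errors <= tab$opportunities))
    ## classification is invariant to a consistent key relabeling
    tab2 <- wcst_error_table(relabel_keys(tr, c(4L, 3L, 1L, 2L)))
    expect_equal(tab2$errors, tab$errors)
    expect_equal(tab2$opportunities, tab$opportunities)
  }
})

test_that("the three-standard-deviation screen excludes extreme appliers only", {
  ## the cohort must be large enough for one subject to sit beyond 3 SD of
  ## a mean that includes it (max standardized residual is (n-1)/sqrt(n))
  set.seed(70)
  n <- 30
  counts <- data.frame(color = c(round(rnorm(n - 1, 50, 2)), 120),
                       shape = rep(50, n), number = rep(50, n))
  scr <- wcst_screen_participants(counts)
  expect_equal(sum(!scr$keep), 1L)
  expect_false(scr$keep[n])
  ## a subject exactly on the boundary is kept
  x <- c(10, 12, 14)
  m <- mean(x); s3 <- 3 * sd(x)
  counts2 <- data.frame(color = c(m - s3, x), shape = rep(10, 4),
                        number = rep(10, 4))
  expect_true(all(wcst_screen_participants(counts2)$keep))
})

test_that("recovery R-squared matches closed-form least squares", {
  grid <- expand.grid(error_type = c("perseveration", "set_loss"),
                      demand = c("repetition", "alternation"),
                      stringsAsFactors = FALSE)
  mk <- function(p) do.call(rbind, lapply(seq_along(p), function(i)
    cbind(subject_id = paste0("s", i), grid, probability = p[i],
          stringsAsFactors = FALSE)))
  obs <- mk(c(0.1, 0.2, 0.3))
  sim <- mk(c(0.2, 0.2, 0.5))
  r2 <- wcst_recovery_r2(obs, sim)
  expect_equal(r2$r_squared, rep(cor(c(0.1, 0.2, 0.3),
                                     c(0.2, 0.2, 0.5))^2, 4))
  expect_equal(r2$r_squared[1], 0.75)
  ## identical with variance: perfect recovery
  expect_equal(wcst_recovery_r2(obs, obs)$r_squared, rep(1, 4))
  ## constant simulation explains nothing
  expect_equal(wcst_recovery_r2(obs, mk(c(0.2, 0.2, 0.2)))$r_squared,
               rep(0, 4))
  expect_error(wcst_recovery_r2(mk(c(0.1, 0.2)), mk(c(0.1, 0.2))),
               "fewer than 3")
})

test_that("one-step-ahead scoring preserves opportunity structure across iterations", {
  p <- table4_wprl()
  tr <- wcst_remove_none(wcst_simulate_agent(p, seed = 44))
  os <- simulate_one_step_ahead(tr, p, n_iter = 30, seed = 45)
  sim_tab <- score_one_step_ahead(os)
  obs_tab <- wcst_error_table(tr)
  expect_equal(sim_tab$opportunities,
               obs_tab$opportunities[match(paste(sim_tab$error_type,
                                                 sim_tab$demand),
                                           paste(obs_tab$error_type,
                                                 obs_tab$demand))])
  pr <- sim_tab$probability[!is.na(sim_tab$probability)]
  expect_true(all(pr >= 0 & pr <= 1))
})
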