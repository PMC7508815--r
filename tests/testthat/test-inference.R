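test_that("the probit transform maps the unconstrained scale as specified", {
  expect_equal(wcst_constrain(0, "unit"), 0.5)
  expect_equal(wcst_constrain(1.96, "unit"), pnorm(1.96))
  expect_lt(abs(wcst_constrain(1.96, "unit") - 0.975), 1e-3)
  expect_equal(wcst_constrain(0, "five"), 2.5)
  ## strictly increasing, numerically invertible on (-6, 6)
  x <- seq(-6, 6, length.out = 201)
  for (kind in c("unit", "five")) {
    y <- wcst_constrain(x, kind)
    expect_true(all(diff(y) > 0))
    expect_equal(wcst_unconstrain(y, kind), x, tolerance = 1e-8)
  }
})

test_that("point estimation is self-consistent, deterministic and beats a grid oracle", {
  tr <- wcst_remove_none(wcst_simulate_agent(default_mbrl(), seed = 41))
  f1 <- fit_subject_point(tr, "mbrl", n_restarts = 4, seed = 42)
  f2 <- fit_subject_point(tr, "mbrl", n_restarts = 4, seed = 42)
  expect_identical(f1, f2)
  ## the reported log-likelihood is exactly the sequence log-likelihood at
  ## the reported parameters
  expect_equal(f1$logLik,
               rl_sequence_loglik(tr, wcst_params("mbrl", f1$par))$total)
  ## on a single trial the optimum is at least as good as a coarse grid
  one <- make_trials(list(c(2, 3, 4)), responses = 2, feedbacks = 1)
  fo <- fit_subject_point(one, "mbrl", n_restarts = 3, seed = 7)
  grid <- expand.grid(a = c(0.2, 0.5, 0.9), g = c(0.2, 0.8),
                      tau = c(0.05, 0.5, 2))
  grid_best <- max(apply(grid, 1, function(r)
    rl_sequence_loglik(one, wcst_params("mbrl", alpha_mb_pos = r[1],
                                        alpha_mb_neg = r[1], gamma_mb = r[2],
                                        tau = r[3]))$total))
  expect_gte(fo$logLik, grid_best)
  expect_gte(fo$logLik, log(1 / 4))
})

test_that("the reduced AU variant fixes focus and positive updating", {
  tr <- wcst_remove_none(wcst_simulate_agent(default_au(), seed = 43))
  f <- fit_subject_point(tr, "au", n_restarts = 3, seed = 44,
                         reduced = TRUE)
  expect_equal(unname(f$par[["f"]]), 1)
  expect_equal(unname(f$par[["p_pos"]]), 0.9999)
  expect_equal(f$logLik,
               au_sequence_loglik(tr, wcst_params("au", f$par))$total)
})

test_that("the temperature is recovered by per-session maximum likelihood", {
  ## absolute learning-rate / inertia scales are weakly identified on
  ## none-filtered sequences (see the methods vignette); the temperature
  ## governs overall choice noise and is recovered reliably
  set.seed(45)
  p <- default_mbrl(tau = 0.1)
  hit <- logical(10)
  for (i in 1:10) {
    tr <- wcst_remove_none(wcst_simulate_agent(p, subject_id = "a"))
    f <- fit_subject_point(tr, "mbrl", n_restarts = 8)
    hit[i] <- abs(f$par[["tau"]] - 0.1) <= 0.2
  }
  expect_gte(mean(hit), 0.8)
})

test_that("the sampler's pooled likelihood equals the module likelihoods", {
  co <- wcst_cohort(3, "prl", n_switches = 6, seed = 46)
  tr <- wcst_remove_none(co$trials)
  subjects <- unique(tr$subject_id)
  set.seed(47)
  theta <- t(replicate(3, {
    kinds <- wcst_param_kinds("prl")
    ifelse(kinds == "five", runif(7, 0.05, 5), runif(7))
  }))
  pooled <- cwcst:::cpp_pooled_loglik(
    tr$card_color, tr$card_shape, tr$card_number, tr$response, tr$feedback,
    match(tr$subject_id, subjects), theta, 2L)
  for (i in seq_along(subjects)) {
    p <- wcst_params("prl", stats::setNames(theta[i, ],
                                            wcst_param_names("prl")))
    ref <- rl_sequence_loglik(tr[tr$subject_id == subjects[i], ], p)$total
    expect_equal(pooled[i], ref, tolerance = 1e-8)
  }
})

test_that("hierarchical estimation runs, bounds its draws and reports diagnostics", {
  co <- wcst_cohort(5, "prl", n_switches = 10, seed = 48)
  tr <- wcst_remove_none(co$trials)
  hf <- suppressWarnings(
    wcst_fit(tr, "prl", method = "mcmc", chains = 2, iter = 300,
             warmup = 150, seed = 49))
  expect_s3_class(hf, "wcst_hfit")
  expect_true(all(is.finite(hf$draws$mu)))
  expect_true(all(hf$draws$sigma > 0))
  kinds <- wcst_param_kinds("prl")
  for (p in seq_along(kinds)) {
    th <- hf$draws$theta[, , , p]
    lim <- if (kinds[[p]] == "five") 5 else 1
    ## the probit transform saturates at double precision for extreme
    ## unconstrained values, so the closed interval is the attainable bound
    expect_true(all(th >= 0 & th <= lim))
  }
  expect_length(hf$rhat, 14L)
  expect_true(all(is.finite(hf$rhat)))
  s <- summary(hf)
  expect_equal(rownames(s$table), wcst_param_names("prl"))
  expect_true(all(s$table$hdi_lower <= s$table$mean &
                    s$table$mean <= s$table$hdi_upper))
  cf <- coef(hf)
  expect_equal(dim(cf), c(5L, 7L))
})

test_that("the highest density interval matches a brute-force shortest interval", {
  expect_equal(wcst_hdi(rep(2.5, 50)), c(2.5, 2.5))
  set.seed(50)
  x <- rnorm(200)^2
  got <- wcst_hdi(x, 0.9)
  ## oracle: scan every candidate interval over the sorted sample
  xs <- sort(x)
  n <- length(xs)
  k <- ceiling(0.9 * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1))
    if (xs[i + k - 1] - xs[i] < best[2] - best[1])
      best <- c(xs[i], xs[i + k - 1])
  expect_equal(got, best)
  ## a symmetric sample maps through the unit transform to about 0.5
  expect_lt(abs(mean(wcst_constrain(rnorm(5000), "unit")) - 0.5), 0.02)
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(51)
  mixed <- matrix(rnorm(2000), 1000, 2)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 3))
  expect_lt(cwcst:::split_rhat(mixed), 1.05)
  expect_gt(cwcst:::split_rhat(apart), 1.5)
})
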