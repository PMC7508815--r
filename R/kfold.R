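#' Random K-fold partition of subjects
#'
#' Seeded uniform partition into K folds whose sizes differ by at most one.
#'
#' @param subjects character vector of subject ids.
#' @param K number of folds (default 5).
#' @param seed optional integer seed.
#' @return named integer vector mapping each subject to a fold in 1..K.
#' @export
kfold_assign <- function(subjects, K = 5, seed = NULL) {
  n <- length(subjects)
  if (!is_count(K, min = 2)) stopf("`K` must be an integer >= 2")
  if (K > n) stopf("K = %d exceeds the number of subjects (%d)", K, n)
  with_seed(seed, {
    stats::setNames(rep_len(seq_len(K), n)[sample.int(n)], subjects)
  })
}

#' Average per-draw likelihoods into an elpd
#'
#' The estimated log predictive density of one held-out subject: the
#' product of predicted response probabilities across the subject's trials
#' is formed per posterior draw, averaged across draws, and logarithmized.
#' Computed stably in log space.
#'
#' @param loglik_draws numeric vector: total log-likelihood of the
#'   subject's sequence under each posterior draw.
#' @return scalar elpd.
#' @examples
#' elpd_average(log(0.125))            # log(0.125)
#' elpd_average(log(c(0.2, 0.4)))      # log(0.3)
#' @export
elpd_average <- function(loglik_draws) {
  log_sum_exp(loglik_draws) - log(length(loglik_draws))
}

#' Held-out elpd of one subject under a training fit
#'
#' For each posterior draw of the training fit's group-level parameters, an
#' individual parameter vector for the unseen subject is constructed —
#' by default by sampling a fresh standardized effect vector
#' \eqn{z \sim N(0,1)} and applying the constraining transform to
#' \eqn{\mu + \sigma z} (\code{method = "sample"}); alternatively the
#' group location is plugged in directly (\eqn{z = 0},
#' \code{method = "plugin"}). The subject's sequence likelihood under each
#' draw is then averaged on the probability scale and logarithmized.
#'
#' @param hfit a \code{wcst_hfit} trained without the held-out subject.
#' @param trials the held-out subject's preprocessed trials.
#' @param method new-subject construction (see above).
#' @param seed optional integer seed for the sampled effects.
#' @return scalar elpd (attribute \code{"n_draws"} records the number of
#'   posterior draws used).
#' @export
heldout_elpd <- function(hfit, trials, method = c("sample", "plugin"),
                         seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(hfit, "wcst_hfit"))
  check_fit_trials(trials, hfit$model)
  if (trials$subject_id[1L] %in% hfit$subjects)
    stopf("subject %s was part of the training fit", trials$subject_id[1L])
  nm <- wcst_param_names(hfit$model)
  kinds <- wcst_param_kinds(hfit$model)
  five <- kinds == "five"
  dm <- dim(hfit$draws$mu)
  S <- dm[1L] * dm[2L]
  mu <- apply(hfit$draws$mu, 3, as.vector)       # S x P
  sigma <- apply(hfit$draws$sigma, 3, as.vector) # S x P
  z <- if (method == "sample") {
    with_seed(seed, matrix(rnorm(S * length(nm)), S, length(nm)))
  } else matrix(0, S, length(nm))
  u <- mu + sigma * z
  theta <- pnorm(u)
  if (any(five)) theta[, five] <- 5 * theta[, five, drop = FALSE]
  ll <- cpp_loglik_by_row(trials$card_color, trials$card_shape,
                          trials$card_number, trials$response,
                          trials$feedback, theta, model_code(hfit$model))
  structure(elpd_average(ll), n_draws = S)
}

#' K-fold cross-validated predictive accuracy
#'
#' Subjects are randomly partitioned into K folds; each model is refitted
#' hierarchically to every training set and the held-out subjects' elpd is
#' computed under the training posterior. Group-level elpd is the sum of
#' per-subject elpd.
#'
#' @param data multi-subject preprocessed \code{wcst_trials}.
#' @param models character vector of model ids to compare.
#' @param K number of folds.
#' @param seed integer seed (partition, sampler and new-subject effects).
#' @param chains,iter,warmup sampler settings passed to the training fits.
#' @param method new-subject construction, see \code{\link{heldout_elpd}}.
#' @return an object of class \code{"wcst_kfold"}: a list with
#'   \code{elpd} (subjects x models matrix), \code{folds}, and the
#'   comparison table of \code{\link{wcst_compare}}.
#' @export
wcst_kfold <- function(data, models = c("wprl", "prl", "mbrl", "au"),
                       K = 5, seed = NULL, chains = 2, iter = 600,
                       warmup = 300, method = c("sample", "plugin")) {
  method <- match.arg(method)
  models <- match.arg(models, several.ok = TRUE)
  subjects <- unique(data$subject_id)
  seed <- seed %||% sample.int(1e6, 1)
  folds <- kfold_assign(subjects, K, seed = seed)
  elpd <- matrix(NA_real_, length(subjects), length(models),
                 dimnames = list(subjects, models))
  for (k in seq_len(K)) {
    test_ids <- names(folds)[folds == k]
    train <- data[!data$subject_id %in% test_ids, , drop = FALSE]
    for (m in models) {
      hf <- fit_hierarchical(train, m, chains = chains, iter = iter,
                             warmup = warmup, seed = seed + 1000L * k)
      for (s in test_ids) {
        tr <- data[data$subject_id == s, , drop = FALSE]
        elpd[s, m] <- heldout_elpd(hf, tr, method = method,
                                   seed = seed + 7L * match(s, subjects))
      }
    }
  }
  comparison <- wcst_compare(elpd)
  structure(list(elpd = elpd, folds = folds, comparison = comparison,
                 models = models, K = K, seed = seed),
            class = "wcst_kfold")
}

#' Compare models by elpd
#'
#' Relative predictive performance: the model with the highest group-level
#' elpd (the lowest absolute elpd, since elpd is negative) is the
#' reference; for every other model the group-level elpd difference
#' (delta-elpd) is reported with its standard error, computed as
#' \eqn{\sqrt{N}} times the sample standard deviation of the per-subject
#' elpd differences. Per-subject winner counts tally each subject's
#' best-predicting model; ties go to the model with the fewest parameters
#' (then first in a fixed order).
#'
#' @param elpd subjects x models matrix of per-subject elpd.
#' @return an object of class \code{"wcst_compare"}: list with
#'   \code{group_elpd}, \code{best}, \code{delta} (data frame of
#'   delta-elpd and SE vs. the best model), and \code{winners}.
#' @examples
#' m <- cbind(a = c(-10, -12), b = c(-11, -11))
#' wcst_compare(m)$delta["b", ]  # delta = 0, se = 2
#' @export
wcst_compare <- function(elpd) {
  stopifnot(is.matrix(elpd), !is.null(colnames(elpd)))
  if (anyNA(elpd)) stopf("per-subject elpd contains missing values")
  models <- colnames(elpd)
  n <- nrow(elpd)
  group <- colSums(elpd)
  best <- models[which.max(group)]
  delta <- do.call(rbind, lapply(models, function(m) {
    d <- elpd[, m] - elpd[, best]
    data.frame(delta_elpd = sum(d),
               se = if (m == best) 0 else sqrt(n) * sd(d))
  }))
  rownames(delta) <- models
  nprm <- vapply(models, function(m) {
    if (m %in% names(MODEL_CODES)) length(wcst_param_names(m))
    else NA_real_ # unknown label: fall back to column order
  }, numeric(1))
  pref <- order(nprm, seq_along(models)) # tie-break: simpler model first
  rank_of <- match(seq_along(models), pref)
  winners <- stats::setNames(integer(length(models)), models)
  for (i in seq_len(n)) {
    top <- which(elpd[i, ] == max(elpd[i, ]))
    w <- top[which.min(rank_of[top])]
    winners[w] <- winners[w] + 1L
  }
  structure(list(group_elpd = group, best = best, delta = delta,
                 winners = winners, n_subjects = n),
            class = "wcst_compare")
}

#' @export
print.wcst_compare <- function(x, digits = 1, ...) {
  cat(sprintf("Model comparison over %d subjects (best: %s)\n",
              x$n_subjects, x$best))
  tab <- cbind(elpd = x$group_elpd, x$delta,
               winners = as.integer(x$winners),
               winner_pct = round(100 * x$winners / x$n_subjects, 1))
  print(round(tab, digits))
  invisible(x)
}

#' @export
print.wcst_kfold <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, models: %s\n", x$K,
              paste(x$models, collapse = ", ")))
  print(x$comparison)
  invisible(x)
}
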