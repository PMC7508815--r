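## Hierarchical Bayesian estimation.
##
## Model (per parameter p, subject i, on the unconstrained scale):
##   mu_p ~ Normal(0, 1)         group location
##   sigma_p ~ half-Cauchy(0, 5) group scale
##   z_ip ~ Normal(0, 1)         standardized individual effect
##   theta_ip = T_p(mu_p + sigma_p * z_ip)   (probit transform; x5 for
##                                            tau / f / d)
## Sampling: adaptive blocked random-walk Metropolis-within-Gibbs — one
## joint proposal per subject over its z vector, one joint proposal per
## parameter over (mu_p, log sigma_p). Proposal scales adapt during warmup
## (Robbins-Monro toward 25% acceptance).

#' Hierarchical Bayesian fit
#'
#' Usually called through \code{\link{wcst_fit}(method = "mcmc")}. Returns
#' posterior draws of group-level locations/scales and individual
#' constrained parameters, with split-Rhat convergence diagnostics (a
#' warning is emitted when any group-level Rhat exceeds
#' \code{rhat_threshold}).
#'
#' @param data multi-subject preprocessed \code{wcst_trials}.
#' @param model model id (\code{"wprl"}, \code{"prl"}, \code{"mbrl"},
#'   \code{"au"}).
#' @param chains,iter,warmup sampler settings; post-warmup draws per chain
#'   are \code{iter - warmup}.
#' @param seed integer seed.
#' @param rhat_threshold convergence warning threshold (default 1.1).
#' @return an object of class \code{"wcst_hfit"} with elements
#'   \code{draws} (\code{mu}, \code{sigma}: S x chains x P arrays;
#'   \code{theta}: S x chains x N x P array of constrained individual
#'   parameters), \code{rhat}, \code{subjects}, \code{model},
#'   \code{accept} and \code{settings}.
#' @export
fit_hierarchical <- function(data, model, chains = 3, iter = 1000,
                             warmup = 500, seed = NULL,
                             rhat_threshold = 1.1) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  if (!is_count(chains) || !is_count(iter) || !is_count(warmup, min = 0) ||
      warmup >= iter)
    stopf("invalid sampler settings (need chains, iter >= 1, 0 <= warmup < iter)")
  subjects <- unique(data$subject_id)
  N <- length(subjects)
  code <- model_code(model)
  nm <- wcst_param_names(model)
  kinds <- wcst_param_kinds(model)
  P <- length(nm)
  five <- kinds == "five"

  ## pooled arrays grouped by subject, plus per-subject slices
  ord <- order(match(data$subject_id, subjects), data$trial_index)
  d <- data[ord, , drop = FALSE]
  for (s in subjects)
    check_fit_trials(d[d$subject_id == s, , drop = FALSE], model)
  subj_idx <- match(d$subject_id, subjects)
  slices <- lapply(seq_len(N), function(i) which(subj_idx == i))

  constrain_mat <- function(u) {
    ## u: N x P unconstrained; returns constrained matrix
    th <- pnorm(u)
    if (any(five)) th[, five] <- 5 * th[, five, drop = FALSE]
    th
  }
  pooled_ll <- function(theta)
    cpp_pooled_loglik(d$card_color, d$card_shape, d$card_number,
                      d$response, d$feedback, subj_idx, theta, code)
  subject_ll <- function(i, theta_i)
    cpp_loglik_by_row(d$card_color[slices[[i]]], d$card_shape[slices[[i]]],
                      d$card_number[slices[[i]]], d$response[slices[[i]]],
                      d$feedback[slices[[i]]],
                      matrix(theta_i, nrow = 1), code)[1L]
  lp_sigma <- function(sig, eta)  # half-Cauchy(0,5) + log-scale Jacobian
    log(2) + dcauchy(sig, 0, 5, log = TRUE) + eta

  S <- iter - warmup
  run_chain <- function(chain_id) {
    mu <- rnorm(P, 0, 0.5)
    eta <- log(0.3) + rnorm(P, 0, 0.3)
    z <- matrix(rnorm(N * P, 0, 0.5), N, P)
    sigma <- exp(eta)
    theta <- constrain_mat(sweep(z, 2, sigma, `*`) +
                             matrix(mu, N, P, byrow = TRUE))
    ll <- pooled_ll(theta)
    if (any(!is.finite(ll)))
      stopf("non-finite likelihood at initialization for subject %s",
            subjects[which(!is.finite(ll))[1L]])
    ls_z <- rep(log(0.15), N)
    ls_g <- rep(log(0.25), P)
    acc_z <- 0; acc_g <- 0; n_z <- 0; n_g <- 0
    ## adaptive joint proposal over all group-level parameters
    ## (mu, log sigma): empirical-covariance random walk, adapted during
    ## warmup; targets correlated (ridge) directions that the
    ## per-parameter blocks mix through slowly
    gvec <- function() c(mu, eta)
    run_mean <- gvec(); run_cov <- diag(0.01, 2 * P); n_run <- 1
    ls_j <- log(0.5)
    chol_j <- chol(run_cov)
    group_logprior <- function(mu_, sigma_, eta_)
      sum(dnorm(mu_, log = TRUE)) + sum(lp_sigma(sigma_, eta_))
    mu_out <- matrix(NA_real_, S, P)
    sg_out <- matrix(NA_real_, S, P)
    th_out <- array(NA_real_, c(S, N, P))
    for (it in seq_len(iter)) {
      adapt <- it <= warmup
      gam <- 1 / (10 + it)^0.6
      ## subject blocks
      for (i in seq_len(N)) {
        zi <- z[i, ]
        zp <- zi + exp(ls_z[i]) * rnorm(P)
        ui <- mu + sigma * zp
        thp <- pnorm(ui)
        thp[five] <- 5 * thp[five]
        llp <- subject_ll(i, thp)
        dlp <- (-0.5 * sum(zp^2) + llp) - (-0.5 * sum(zi^2) + ll[i])
        a <- min(1, exp(dlp))
        if (is.finite(dlp) && runif(1) < a) {
          z[i, ] <- zp; theta[i, ] <- thp; ll[i] <- llp
        }
        if (adapt) ls_z[i] <- ls_z[i] + gam * (a - 0.25)
        else { acc_z <- acc_z + a; n_z <- n_z + 1 }
      }
      ## group blocks
      for (p in seq_len(P)) {
        step <- exp(ls_g[p]) * rnorm(2)
        mup <- mu[p] + step[1L]
        etap <- eta[p] + step[2L]
        sigp <- exp(etap)
        up <- mup + sigp * z[, p]
        thcol <- pnorm(up)
        if (five[p]) thcol <- 5 * thcol
        thp <- theta
        thp[, p] <- thcol
        llp <- pooled_ll(thp)
        dlp <- (dnorm(mup, log = TRUE) + lp_sigma(sigp, etap) + sum(llp)) -
               (dnorm(mu[p], log = TRUE) + lp_sigma(sigma[p], eta[p]) +
                  sum(ll))
        a <- min(1, exp(dlp))
        if (is.finite(dlp) && runif(1) < a) {
          mu[p] <- mup; eta[p] <- etap; sigma[p] <- sigp
          theta <- thp; ll <- llp
        }
        if (adapt) ls_g[p] <- ls_g[p] + gam * (a - 0.25)
        else { acc_g <- acc_g + a; n_g <- n_g + 1 }
      }
      ## joint group move
      {
        step <- exp(ls_j) * as.vector(rnorm(2 * P) %*% chol_j)
        mup <- mu + step[seq_len(P)]
        etap <- eta + step[P + seq_len(P)]
        sigp <- exp(etap)
        up <- matrix(mup, N, P, byrow = TRUE) +
          sweep(z, 2, sigp, `*`)
        thp <- constrain_mat(up)
        llp <- pooled_ll(thp)
        dlp <- (group_logprior(mup, sigp, etap) + sum(llp)) -
               (group_logprior(mu, sigma, eta) + sum(ll))
        a <- min(1, exp(dlp))
        if (is.finite(dlp) && runif(1) < a) {
          mu <- mup; eta <- etap; sigma <- sigp; theta <- thp; ll <- llp
        }
        if (adapt) {
          ls_j <- ls_j + gam * (a - 0.25)
          g <- gvec()
          n_run <- n_run + 1
          dlt <- g - run_mean
          run_mean <- run_mean + dlt / n_run
          run_cov <- run_cov * (n_run - 2) / (n_run - 1) +
            tcrossprod(dlt) / n_run
          if (it > 50 && it %% 25 == 0)
            chol_j <- tryCatch(
              chol(run_cov / (2 * P) + diag(1e-6, 2 * P)),
              error = function(e) chol_j)
        }
      }
      if (it > warmup) {
        s <- it - warmup
        mu_out[s, ] <- mu
        sg_out[s, ] <- sigma
        th_out[s, , ] <- theta
      }
    }
    list(mu = mu_out, sigma = sg_out, theta = th_out,
         accept = c(subject = acc_z / max(n_z, 1),
                    group = acc_g / max(n_g, 1)))
  }

  res <- with_seed(seed, lapply(seq_len(chains), run_chain))

  mu_d <- array(NA_real_, c(S, chains, P),
                dimnames = list(NULL, NULL, nm))
  sg_d <- mu_d
  th_d <- array(NA_real_, c(S, chains, N, P),
                dimnames = list(NULL, NULL, subjects, nm))
  for (c in seq_len(chains)) {
    mu_d[, c, ] <- res[[c]]$mu
    sg_d[, c, ] <- res[[c]]$sigma
    th_d[, c, , ] <- res[[c]]$theta
  }
  rhat <- c(
    stats::setNames(vapply(seq_len(P), function(p)
      split_rhat(mu_d[, , p, drop = FALSE][, , 1L]), numeric(1)),
      paste0("mu_", nm)),
    stats::setNames(vapply(seq_len(P), function(p)
      split_rhat(sg_d[, , p, drop = FALSE][, , 1L]), numeric(1)),
      paste0("sigma_", nm)))
  if (any(rhat > rhat_threshold, na.rm = TRUE))
    warning(sprintf(
      "possible non-convergence: Rhat > %.2f for %s",
      rhat_threshold,
      paste(names(rhat)[which(rhat > rhat_threshold)], collapse = ", ")),
      call. = FALSE)
  structure(list(model = model, method = "mcmc",
                 draws = list(mu = mu_d, sigma = sg_d, theta = th_d),
                 rhat = rhat, subjects = subjects, data = d,
                 accept = lapply(res, `[[`, "accept"),
                 settings = list(chains = chains, iter = iter,
                                 warmup = warmup, seed = seed)),
            class = "wcst_hfit")
}

## split-Rhat (Gelman et al.): halve each chain, compare within/between
split_rhat <- function(draws) {
  ## draws: iterations x chains
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[seq.int(n - half + 1, n), , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Highest density interval
#'
#' Shortest interval containing a given probability mass of a sample.
#'
#' @param x numeric sample.
#' @param prob probability mass (default 0.95).
#' @return numeric vector \code{c(lower, upper)}.
#' @export
wcst_hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(c(NA_real_, NA_real_))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[seq.int(k, n)] - x[seq_len(n - k + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1L])
}

#' Posterior summary of group-level locations
#'
#' Summarizes the constrained group-level location parameters, i.e. the
#' probit transform of the group location draws (times five for
#' temperature / focus / consistency) — the scale on which group-level
#' parameter tables are conventionally reported for these models.
#'
#' @param object a \code{wcst_hfit}.
#' @param prob HDI probability mass.
#' @param ... unused.
#' @return a data frame with \code{mean}, \code{sd}, \code{hdi_lower},
#'   \code{hdi_upper} and \code{rhat} per parameter.
#' @export
summary.wcst_hfit <- function(object, prob = 0.95, ...) {
  nm <- wcst_param_names(object$model)
  kinds <- wcst_param_kinds(object$model)
  tab <- do.call(rbind, lapply(seq_along(nm), function(p) {
    mu <- as.vector(object$draws$mu[, , p])
    con <- wcst_constrain(mu, kinds[[p]])
    h <- wcst_hdi(con, prob)
    data.frame(mean = mean(con), sd = sd(con),
               hdi_lower = h[1L], hdi_upper = h[2L],
               rhat = object$rhat[[paste0("mu_", nm[p])]])
  }))
  rownames(tab) <- nm
  structure(list(model = object$model, table = tab,
                 settings = object$settings,
                 n_subjects = length(object$subjects)),
            class = "summary.wcst_hfit")
}

#' @export
print.summary.wcst_hfit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Hierarchical Bayesian %s fit: %d subjects, %d chains x %d iter (%d warmup)\n",
    x$model, x$n_subjects, x$settings$chains, x$settings$iter,
    x$settings$warmup))
  cat("constrained group-level locations:\n")
  print(round(x$table, digits))
  invisible(x)
}

#' @export
print.wcst_hfit <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' @export
coef.wcst_hfit <- function(object, ...) {
  ## posterior-mean constrained individual parameters, subjects x params
  apply(object$draws$theta, c(3, 4), mean)
}

#' @export
plot.wcst_hfit <- function(x, ...) {
  nm <- wcst_param_names(x$model)
  kinds <- wcst_param_kinds(x$model)
  op <- par(mfrow = grDevices::n2mfrow(length(nm)), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (p in seq_along(nm)) {
    con <- wcst_constrain(as.vector(x$draws$mu[, , p]), kinds[[p]])
    plot(stats::density(con), main = nm[p], xlab = "constrained location")
  }
  invisible(x)
}
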