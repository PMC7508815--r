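#' Remove responses that match no sorting category
#'
#' Trials on which the executed key is the card's unmatched key apply no
#' category; they receive probability zero under the attentional-updating
#' model and are removed from all analyses. Original trial indices are
#' kept, so the gap left by a removed trial marks its successor as
#' unscorable for error classification.
#'
#' @param trials a \code{wcst_trials} data frame (any number of subjects).
#' @return the filtered data frame, with attribute \code{removal_report}:
#'   a data frame of removed (subject, trial_index) pairs, plus attribute
#'   \code{removal_fraction}.
#' @export
wcst_remove_none <- function(trials) {
  applied <- applied_of(trials)
  drop <- applied == "none"
  report <- trials[drop, c("subject_id", "trial_index"), drop = FALSE]
  rownames(report) <- NULL
  out <- trials[!drop, , drop = FALSE]
  out <- as_wcst_trials(out, removal_report = report,
                        removal_fraction = mean(drop))
  out
}

#' Classify trials into error types and response demands
#'
#' Scores every trial (except the first of a subject and trials whose
#' predecessor was removed) against its predecessor:
#' \itemize{
#'   \item after \emph{negative} feedback the trial is a perseveration
#'     opportunity; repeating the previously applied category is a
#'     perseveration error.
#'   \item after \emph{positive} feedback the trial is a set-loss
#'     opportunity; switching the applied category is a set-loss error.
#' }
#' Response demand follows from where the previously executed key maps on
#' the current card: if it maps to the previously applied category, the
#' error response after negative feedback (and the correct response after
#' positive feedback) repeats the key — demanded alternation and demanded
#' repetition, respectively; if it maps to a different category the demands
#' reverse; if it maps to no category the trial's demand is unclassified.
#' With \code{demand_rule = "target"}, post-negative demand is instead
#' scored against the key of the scheduled target category (repetition if
#' that key equals the previous key, alternation if the category-repeating
#' key does).
#'
#' @param trials one subject's trials (none-category responses removed).
#' @param demand_rule \code{"any_switch"} (default) or \code{"target"}.
#' @return a data frame with one row per trial: \code{scored},
#'   \code{error_type} (opportunity type: \code{"perseveration"},
#'   \code{"set_loss"} or \code{NA} for unscored trials), \code{demand}
#'   (\code{"repetition"}, \code{"alternation"}, \code{"unclassified"}),
#'   and \code{error} (logical).
#' @export
wcst_classify <- function(trials, demand_rule = c("any_switch", "target")) {
  demand_rule <- match.arg(demand_rule)
  if (length(unique(trials$subject_id)) > 1L)
    stopf("classification takes one subject at a time")
  n <- nrow(trials)
  applied <- applied_of(trials)
  if (any(applied == "none"))
    stopf("remove none-category responses first (wcst_remove_none)")
  out <- data.frame(
    trial_index = trials$trial_index,
    scored = FALSE,
    error_type = NA_character_,
    demand = NA_character_,
    error = NA,
    stringsAsFactors = FALSE)
  if (n < 2L) return(out)
  for (t in 2:n) {
    if (trials$trial_index[t] != trials$trial_index[t - 1L] + 1L) next
    prev_fb <- trials$feedback[t - 1L]
    prev_app <- applied[t - 1L]
    prev_key <- trials$response[t - 1L]
    card <- c(trials$card_color[t], trials$card_shape[t],
              trials$card_number[t])
    prev_key_cat <- wcst_applied_category(card, prev_key)
    out$scored[t] <- TRUE
    if (prev_fb < 0) {
      out$error_type[t] <- "perseveration"
      out$error[t] <- applied[t] == prev_app
      out$demand[t] <- if (demand_rule == "any_switch") {
        if (prev_key_cat == "none") "unclassified"
        else if (prev_key_cat == prev_app) "alternation"
        else "repetition"
      } else {
        target_key <- card[[match(trials$target_category[t],
                                  WCST_CATEGORIES)]]
        if (target_key == prev_key) "repetition"
        else if (prev_key_cat == prev_app) "alternation"
        else "unclassified"
      }
    } else {
      out$error_type[t] <- "set_loss"
      out$error[t] <- applied[t] != prev_app
      out$demand[t] <- if (prev_key_cat == "none") "unclassified"
        else if (prev_key_cat == prev_app) "repetition"
        else "alternation"
    }
  }
  out
}

#' Conditional error probabilities of one subject
#'
#' Counts errors and opportunities per (error type x response demand) cell
#' and divides; cells without opportunities are flagged missing rather than
#' zero. The modulation contrast — the perseveration probability under
#' demanded repetition minus under demanded alternation — is attached.
#'
#' @inheritParams wcst_classify
#' @return an object of class \code{"wcst_error_table"}: a data frame with
#'   columns \code{error_type}, \code{demand}, \code{errors},
#'   \code{opportunities}, \code{probability} (4 rows), with attributes
#'   \code{subject_id} and \code{modulation} (the contrast, \code{NA} if
#'   either cell is missing).
#' @export
wcst_error_table <- function(trials, demand_rule = c("any_switch", "target")) {
  if (nrow(trials) == 0L) stopf("empty trial data")
  cls <- wcst_classify(trials, demand_rule = demand_rule)
  cells <- expand.grid(error_type = c("set_loss", "perseveration"),
                       demand = c("repetition", "alternation"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- cls$scored & cls$error_type == cells$error_type[i] &
      cls$demand == cells$demand[i]
    sel[is.na(sel)] <- FALSE
    opp <- sum(sel)
    err <- sum(cls$error[sel])
    data.frame(error_type = cells$error_type[i], demand = cells$demand[i],
               errors = err, opportunities = opp,
               probability = if (opp > 0) err / opp else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  p <- function(et, dm)
    tab$probability[tab$error_type == et & tab$demand == dm]
  structure(tab,
            subject_id = trials$subject_id[1L],
            modulation = p("perseveration", "repetition") -
              p("perseveration", "alternation"),
            class = c("wcst_error_table", "data.frame"))
}

#' Cohort-level behavioral scoring
#'
#' Applies \code{\link{wcst_error_table}} to every subject and aggregates:
#' group mean conditional error probabilities per cell (subjects lacking a
#' cell are dropped from that cell's mean), overall perseveration and
#' set-loss propensities (pooled over demands within subject), and the
#' group-mean modulation contrast.
#'
#' @param trials multi-subject \code{wcst_trials} (none-category responses
#'   removed).
#' @param demand_rule see \code{\link{wcst_classify}}.
#' @return an object of class \code{"wcst_score"}: list with
#'   \code{per_subject} (long data frame of cell probabilities),
#'   \code{group} (cell means), \code{propensity} (per-subject pooled
#'   perseveration/set-loss probabilities) and \code{modulation}
#'   (per-subject contrasts).
#' @export
wcst_score <- function(trials, demand_rule = c("any_switch", "target")) {
  demand_rule <- match.arg(demand_rule)
  subjects <- unique(trials$subject_id)
  per <- lapply(subjects, function(s) {
    tab <- wcst_error_table(trials[trials$subject_id == s, , drop = FALSE],
                            demand_rule = demand_rule)
    cbind(subject_id = s, as.data.frame(tab),
          stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  group <- stats::aggregate(probability ~ error_type + demand, data = per,
                            FUN = mean, na.rm = TRUE, na.action = NULL)
  pooled <- do.call(rbind, lapply(split(per, per$subject_id), function(df) {
    data.frame(
      subject_id = df$subject_id[1L],
      perseveration = {
        sel <- df$error_type == "perseveration"
        if (sum(df$opportunities[sel]) > 0)
          sum(df$errors[sel]) / sum(df$opportunities[sel]) else NA_real_
      },
      set_loss = {
        sel <- df$error_type == "set_loss"
        if (sum(df$opportunities[sel]) > 0)
          sum(df$errors[sel]) / sum(df$opportunities[sel]) else NA_real_
      },
      stringsAsFactors = FALSE)
  }))
  modulation <- vapply(split(per, per$subject_id), function(df) {
    pr <- function(dm)
      df$probability[df$error_type == "perseveration" & df$demand == dm]
    pr("repetition") - pr("alternation")
  }, numeric(1))
  structure(list(per_subject = per, group = group, propensity = pooled,
                 modulation = modulation, demand_rule = demand_rule),
            class = "wcst_score")
}

#' @export
print.wcst_score <- function(x, digits = 3, ...) {
  cat("Group mean conditional error probabilities:\n")
  print(transform(x$group, probability = round(probability, digits)))
  cat(sprintf(
    "mean perseveration %.3f, mean set-loss %.3f, mean modulation %+.3f\n",
    mean(x$propensity$perseveration, na.rm = TRUE),
    mean(x$propensity$set_loss, na.rm = TRUE),
    mean(x$modulation, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.wcst_score <- function(x, ...) {
  g <- x$group
  m <- matrix(g$probability[order(g$error_type, g$demand)], nrow = 2,
              dimnames = list(sort(unique(g$demand)),
                              sort(unique(g$error_type))))
  barplot(m, beside = TRUE, legend.text = rownames(m),
          ylab = "conditional error probability", ...)
  invisible(x)
}

#' Participant validity screen
#'
#' A subject's test performance is invalid when, for any sorting category,
#' their number of applications of that category lies strictly outside the
#' cohort mean plus/minus three standard deviations for that category
#' (values exactly on the boundary are kept).
#'
#' @param trials multi-subject \code{wcst_trials}, or a numeric matrix /
#'   data frame of per-subject application counts with columns
#'   \code{color}, \code{shape}, \code{number} (one row per subject).
#' @return a data frame with one row per subject: per-category application
#'   counts and a logical \code{keep}.
#' @export
wcst_screen_participants <- function(trials) {
  if (all(WCST_CATEGORIES %in% colnames(trials)) &&
      !"subject_id" %in% colnames(trials)) {
    counts <- as.matrix(trials[, WCST_CATEGORIES])
    subjects <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  } else {
    subjects <- unique(trials$subject_id)
    applied <- applied_of(trials)
    counts <- t(vapply(subjects, function(s) {
      a <- applied[trials$subject_id == s]
      vapply(WCST_CATEGORIES, function(k) sum(a == k), numeric(1))
    }, numeric(3)))
  }
  if (nrow(counts) < 2L) stopf("the screen needs at least 2 subjects")
  mu <- colMeans(counts)
  sdev <- apply(counts, 2, sd)
  lo <- mu - 3 * sdev
  hi <- mu + 3 * sdev
  keep <- apply(counts, 1, function(x) all(x >= lo & x <= hi))
  data.frame(subject_id = subjects, counts, keep = keep,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Recovery of inter-individual variance (R-squared)
#'
#' Least-squares R-squared of observed conditional error probabilities
#' predicted by simulated ones, per (error type x demand) cell; missing
#' cells are dropped pairwise.
#'
#' @param observed,simulated long per-subject cell tables as produced by
#'   \code{\link{wcst_score}$per_subject} (columns \code{subject_id},
#'   \code{error_type}, \code{demand}, \code{probability}).
#' @return a data frame with one row per cell and column \code{r_squared}.
#' @export
wcst_recovery_r2 <- function(observed, simulated) {
  key <- c("subject_id", "error_type", "demand")
  m <- merge(observed[, c(key, "probability")],
             simulated[, c(key, "probability")],
             by = key, suffixes = c("_obs", "_sim"))
  cells <- unique(m[, c("error_type", "demand")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- m$error_type == cells$error_type[i] &
      m$demand == cells$demand[i] &
      is.finite(m$probability_obs) & is.finite(m$probability_sim)
    d <- m[sel, ]
    if (nrow(d) < 3L)
      stopf("fewer than 3 paired subjects in cell %s/%s",
            cells$error_type[i], cells$demand[i])
    r2 <- if (var(d$probability_sim) == 0 ||
              var(d$probability_obs) == 0) 0 else {
      fit <- lm(probability_obs ~ probability_sim, data = d)
      y <- d$probability_obs
      1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
    }
    data.frame(error_type = cells$error_type[i], demand = cells$demand[i],
               n = nrow(d), r_squared = r2, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Score one-trial-ahead simulations into conditional error probabilities
#'
#' For every simulated iteration, each scored trial keeps its observed
#' predecessor (feedback, applied category, executed key) and its observed
#' card — so opportunity type and response demand are fixed across
#' iterations — while the error indicator comes from the simulated
#' response's applied category. Cell probabilities are computed per
#' iteration and averaged across iterations. Simulated responses matching
#' no category (possible for RL agents, never for AU) count as category
#' switches.
#'
#' @param onestep a \code{wcst_onestep} object.
#' @param demand_rule see \code{\link{wcst_classify}}.
#' @return a \code{wcst_error_table}-shaped data frame of iteration-mean
#'   cell probabilities for the simulated behavior.
#' @export
score_one_step_ahead <- function(onestep,
                                 demand_rule = c("any_switch", "target")) {
  stopifnot(inherits(onestep, "wcst_onestep"))
  obs <- onestep$observed
  cls <- wcst_classify(obs, demand_rule = demand_rule)
  applied_prev <- applied_of(obs)
  sim <- onestep$responses # iter x T
  cards <- as.matrix(obs[, c("card_color", "card_shape", "card_number")])
  cells <- expand.grid(error_type = c("set_loss", "perseveration"),
                       demand = c("repetition", "alternation"),
                       stringsAsFactors = FALSE)
  n_iter <- nrow(sim)
  ## applied category index of each simulated response (0 = none)
  sim_applied <- matrix(0L, n_iter, ncol(sim))
  for (d in 1:3) {
    hit <- sweep(sim, 2, cards[, d], `==`)
    sim_applied[hit] <- d
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- which(cls$scored & cls$error_type == cells$error_type[i] &
                   cls$demand == cells$demand[i])
    if (length(sel) == 0L)
      return(data.frame(error_type = cells$error_type[i],
                        demand = cells$demand[i], opportunities = 0,
                        probability = NA_real_, stringsAsFactors = FALSE))
    prev_app_idx <- match(applied_prev[sel - 1L], WCST_CATEGORIES)
    rep_mat <- sweep(sim_applied[, sel, drop = FALSE], 2, prev_app_idx,
                     `==`)
    err <- if (cells$error_type[i] == "perseveration") rep_mat else !rep_mat
    data.frame(error_type = cells$error_type[i], demand = cells$demand[i],
               opportunities = length(sel),
               probability = mean(rowMeans(err)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
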