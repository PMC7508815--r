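#' The cWCST stimulus deck
#'
#' The computerized Wisconsin Card Sorting Test uses four key cards (key
#' \eqn{k} shows \eqn{k} items of color \eqn{k} and shape \eqn{k}, so key
#' \eqn{k} has color-, shape- and number-index \eqn{k}) and a deck of
#' stimulus cards described by a (color, shape, number) triple of key
#' indices. Deck-valid cards share at most one dimension with any key card,
#' i.e. the three attribute indices are pairwise distinct. Exactly 24 such
#' cards exist; each matches three distinct key cards on exactly one
#' dimension each and one key card on no dimension (the "unmatched" key),
#' which makes the applied sorting category unambiguous.
#'
#' @return a data frame with integer columns \code{color}, \code{shape},
#'   \code{number} (24 rows, lexicographic order).
#' @examples
#' nrow(wcst_deck())  # 24
#' @export
wcst_deck <- function() {
  g <- expand.grid(number = 1:4, shape = 1:4, color = 1:4)
  g <- g[g$color != g$shape & g$color != g$number & g$shape != g$number, ]
  g <- g[order(g$color, g$shape, g$number), c("color", "shape", "number")]
  rownames(g) <- NULL
  g
}

#' Applied sorting category of a response
#'
#' A response (key press) applies the unique category on whose dimension
#' the stimulus card matches that key card, or no category at all when the
#' key is the card's unmatched key.
#'
#' @param card integer vector \code{c(color, shape, number)} of key indices
#'   (pairwise distinct), or a one-row data frame with those columns.
#' @param response key index in 1..4.
#' @return \code{"color"}, \code{"shape"}, \code{"number"}, or
#'   \code{"none"}.
#' @examples
#' wcst_applied_category(c(2, 3, 4), 2)  # "color"
#' wcst_applied_category(c(2, 3, 4), 1)  # "none"
#' @export
wcst_applied_category <- function(card, response) {
  card <- as_card(card)
  if (!is_count(response) || response > 4)
    stopf("`response` must be a key index in 1..4")
  d <- which(card == response)
  if (length(d) == 0L) "none" else WCST_CATEGORIES[d]
}

as_card <- function(card) {
  if (is.data.frame(card))
    card <- c(card$color[1L], card$shape[1L], card$number[1L])
  card <- as.integer(card)
  if (length(card) != 3L || anyNA(card) || any(card < 1L | card > 4L))
    stopf("a card is a triple of key indices in 1..4")
  if (anyDuplicated(card))
    stopf("invalid card (%s): attribute indices must be pairwise distinct",
          paste(card, collapse = ","))
  card
}

#' Feedback rule
#'
#' Positive feedback (+1) is given if and only if the applied category
#' equals the scheduled target category; any other applied category, and a
#' response matching no category, receives negative feedback (-1).
#'
#' @param applied applied category (\code{"color"}, \code{"shape"},
#'   \code{"number"} or \code{"none"}).
#' @param target target category.
#' @return \code{+1L} or \code{-1L}.
#' @export
wcst_feedback <- function(applied, target) {
  if (!target %in% WCST_CATEGORIES) stopf("invalid target category")
  if (!applied %in% c(WCST_CATEGORIES, "none"))
    stopf("invalid applied category")
  if (identical(applied, target)) 1L else -1L
}

#' Category-switch schedule
#'
#' Generates the sequence of sorting-category episodes for a cWCST session.
#' The correct category changes after a run of consecutive correct sorts
#' whose required length (the switch criterion) is drawn per episode; the
#' criterion distribution defaults to uniform on \{2, 3, 4, 5\}, giving the
#' task's mean of 3.5 correct repetitions per switch. Each new target is
#' drawn uniformly from the two categories other than the current one; the
#' first target is uniform over all three.
#'
#' @param n_switches number of category switches the session must complete
#'   (default 41; the generated schedule carries \code{n_switches + 1}
#'   episodes so a target is defined after the final switch).
#' @param max_trials session trial cap (default 250).
#' @param criteria either \code{NULL} (default sampler, uniform on 2..5), a
#'   function \code{function(n)} returning \code{n} integer criteria
#'   \eqn{\ge 2}, or an integer vector of length \code{n_switches + 1}.
#' @param practice if \code{TRUE}, a practice schedule (6 switches) is
#'   generated and flagged; practice sessions are excluded from analyses.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return an object of class \code{"wcst_schedule"}: a data frame with
#'   columns \code{target} and \code{criterion}, and attributes
#'   \code{n_switches}, \code{max_trials}, \code{practice}.
#' @examples
#' s <- wcst_schedule(seed = 1)
#' mean(s$criterion)
#' @export
wcst_schedule <- function(n_switches = 41, max_trials = 250,
                          criteria = NULL, practice = FALSE, seed = NULL) {
  if (isTRUE(practice)) n_switches <- 6
  if (!is_count(n_switches, min = 1))
    stopf("`n_switches` must be a positive integer")
  if (!is_count(max_trials, min = 1))
    stopf("`max_trials` must be a positive integer")
  n_ep <- n_switches + 1L
  with_seed(seed, {
    crit <- if (is.null(criteria)) {
      sample(2:5, n_ep, replace = TRUE)
    } else if (is.function(criteria)) {
      as.integer(criteria(n_ep))
    } else {
      as.integer(criteria)
    }
    if (length(crit) != n_ep)
      stopf("`criteria` must provide %d values", n_ep)
    if (anyNA(crit) || any(crit < 2L))
      stopf("every switch criterion must be an integer >= 2")
    targets <- character(n_ep)
    targets[1L] <- sample(WCST_CATEGORIES, 1L)
    for (i in seq_len(n_ep - 1L))
      targets[i + 1L] <- sample(setdiff(WCST_CATEGORIES, targets[i]), 1L)
    structure(
      data.frame(target = targets, criterion = crit,
                 stringsAsFactors = FALSE),
      n_switches = as.integer(n_switches),
      max_trials = as.integer(max_trials),
      practice = isTRUE(practice),
      class = c("wcst_schedule", "data.frame"))
  })
}

#' Administer a cWCST session to a policy
#'
#' Runs the trial loop: on each trial a stimulus card is drawn uniformly
#' from the deck (no immediate repetition of the previous card), the policy
#' chooses a key, the applied category and feedback are derived, and the
#' scheduled target advances once the current episode's criterion run of
#' consecutive correct sorts is reached. The session ends after the
#' required number of switches or at the trial cap, whichever comes first.
#'
#' @param policy a function \code{function(card, info)} returning a key
#'   index in 1..4. \code{info} is a list with elements \code{trial}
#'   (1-based index), \code{target} (current target category),
#'   \code{last} (previous trial's record as a list, or \code{NULL}) and
#'   \code{history} (list of all previous records).
#' @param schedule a \code{\link{wcst_schedule}}.
#' @param subject_id subject label for the returned trial log.
#' @param seed optional integer seed for the card draws (and any
#'   randomness inside the policy).
#' @return a \code{wcst_trials} data frame (one row per trial) with columns
#'   \code{subject_id}, \code{trial_index}, \code{card_color},
#'   \code{card_shape}, \code{card_number}, \code{response},
#'   \code{feedback}, \code{target_category}, \code{applied_category},
#'   \code{switch_number}, and attributes \code{completed_switches} and
#'   \code{truncated} (\code{TRUE} when the trial cap ended the session
#'   before all switches were completed).
#' @examples
#' s <- wcst_schedule(n_switches = 5, seed = 1)
#' trials <- wcst_session(wcst_policy_oracle(), s, seed = 2)
#' nrow(trials) == sum(s$criterion[1:5])
#' @export
wcst_session <- function(policy, schedule, subject_id = "s1", seed = NULL) {
  stopifnot(is.function(policy), inherits(schedule, "wcst_schedule"))
  n_sw <- attr(schedule, "n_switches")
  max_t <- attr(schedule, "max_trials")
  deck <- as.matrix(wcst_deck())
  with_seed(seed, {
    card_col <- integer(max_t); card_shp <- integer(max_t)
    card_num <- integer(max_t); resp <- integer(max_t)
    fb <- integer(max_t); targ <- character(max_t)
    appl <- character(max_t); swn <- integer(max_t)
    history <- vector("list", max_t)
    ep <- 1L; run <- 0L; switches <- 0L; t <- 0L; prev_card <- 0L
    while (switches < n_sw && t < max_t) {
      t <- t + 1L
      repeat {
        i <- sample.int(24L, 1L)
        if (i != prev_card) break
      }
      prev_card <- i
      card <- deck[i, ]
      target <- schedule$target[ep]
      info <- list(trial = t, target = target,
                   last = if (t > 1L) history[[t - 1L]] else NULL,
                   history = if (t > 1L) history[seq_len(t - 1L)] else list())
      r <- policy(card, info)
      if (!is_count(r) || r > 4)
        stopf("policy returned an invalid response on trial %d", t)
      r <- as.integer(r)
      a <- wcst_applied_category(card, r)
      f <- wcst_feedback(a, target)
      card_col[t] <- card[[1L]]; card_shp[t] <- card[[2L]]
      card_num[t] <- card[[3L]]; resp[t] <- r; fb[t] <- f
      targ[t] <- target; appl[t] <- a; swn[t] <- switches
      history[[t]] <- list(card = card, response = r, feedback = f,
                           applied = a, target = target)
      if (f == 1L) {
        run <- run + 1L
        if (run == schedule$criterion[ep]) {
          ep <- ep + 1L; run <- 0L; switches <- switches + 1L
        }
      } else run <- 0L
    }
    idx <- seq_len(t)
    out <- data.frame(
      subject_id = subject_id, trial_index = idx,
      card_color = card_col[idx], card_shape = card_shp[idx],
      card_number = card_num[idx], response = resp[idx],
      feedback = fb[idx], target_category = targ[idx],
      applied_category = appl[idx], switch_number = swn[idx],
      stringsAsFactors = FALSE)
    as_wcst_trials(out, completed_switches = switches,
                   truncated = switches < n_sw)
  })
}

as_wcst_trials <- function(df, ...) {
  extras <- list(...)
  for (nm in names(extras)) attr(df, nm) <- extras[[nm]]
  class(df) <- unique(c("wcst_trials", class(df)))
  df
}

#' Built-in response policies
#'
#' \code{wcst_policy_oracle} always sorts by the scheduled target category;
#' \code{wcst_policy_random} presses a uniformly random key;
#' \code{wcst_policy_unmatched} always presses the card's unmatched key
#' (and therefore never earns positive feedback). Agent policies driven by
#' the cognitive models are built with \code{\link{wcst_agent_policy}}.
#'
#' @return a policy function for \code{\link{wcst_session}}.
#' @export
wcst_policy_oracle <- function() {
  function(card, info) card[[match(info$target, WCST_CATEGORIES)]]
}

#' @rdname wcst_policy_oracle
#' @export
wcst_policy_random <- function() {
  function(card, info) sample.int(4L, 1L)
}

#' @rdname wcst_policy_oracle
#' @export
wcst_policy_unmatched <- function() {
  function(card, info) setdiff(1:4, card)[1L]
}
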