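## canonical trial-log column order
TRIAL_LOG_COLUMNS <- c("subject_id", "trial_index", "card_color",
                       "card_shape", "card_number", "response", "feedback",
                       "target_category", "applied_category")

#' Read a cWCST trial log
#'
#' Reads a comma-delimited trial log (one row per trial; see
#' \code{\link{write_wcst}} for the column layout), validates it, and
#' returns trials grouped by subject and sorted by trial index. In strict
#' mode (default) any invariant violation — non-distinct card attributes,
#' out-of-range codes, an applied category inconsistent with (card,
#' response), feedback inconsistent with (applied, target) — is an error
#' naming the offending row; in lenient mode the applied category and
#' feedback are recomputed from the raw fields with a warning.
#'
#' @param path file path.
#' @param strict logical (default \code{TRUE}).
#' @return a \code{wcst_trials} data frame.
#' @export
read_wcst <- function(path, strict = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(df))
  if (length(missing))
    stopf("trial log lacks column(s): %s", paste(missing, collapse = ", "))
  df <- df[, TRIAL_LOG_COLUMNS]
  rowid <- seq_len(nrow(df)) + 1L # header is line 1
  bad_range <- !(df$card_color %in% 1:4) | !(df$card_shape %in% 1:4) |
    !(df$card_number %in% 1:4) | !(df$response %in% 1:4) |
    !(df$feedback %in% c(-1L, 1L)) |
    !(df$target_category %in% WCST_CATEGORIES) |
    !(df$applied_category %in% c(WCST_CATEGORIES, "none"))
  if (any(bad_range))
    stopf("out-of-range values in row(s) %s",
          paste(head(rowid[bad_range], 5), collapse = ", "))
  dup <- df$card_color == df$card_shape | df$card_color == df$card_number |
    df$card_shape == df$card_number
  if (any(dup))
    stopf("non-distinct card attributes in row(s) %s",
          paste(head(rowid[dup], 5), collapse = ", "))
  applied <- applied_of(df)
  fb <- ifelse(applied == df$target_category, 1L, -1L)
  mism <- applied != df$applied_category | fb != df$feedback
  if (any(mism)) {
    if (strict)
      stopf("inconsistent applied category or feedback in row(s) %s",
            paste(head(rowid[mism], 5), collapse = ", "))
    warning(sprintf(
      "recomputed applied category / feedback for %d row(s)", sum(mism)),
      call. = FALSE)
    df$applied_category <- applied
    df$feedback <- fb
  }
  df <- df[order(match(df$subject_id, unique(df$subject_id)),
                 df$trial_index), , drop = FALSE]
  rownames(df) <- NULL
  as_wcst_trials(df)
}

#' Write a cWCST trial log
#'
#' Serializes trials to comma-delimited UTF-8 text in the canonical column
#' order (subject_id, trial_index, card_color, card_shape, card_number,
#' response, feedback, target_category, applied_category), with subjects
#' in sorted order and trials in chronological order; write-read-write
#' round trips are byte-identical.
#'
#' @param trials a \code{wcst_trials} data frame (or a
#'   \code{\link{wcst_cohort}}, whose trials are written).
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_wcst <- function(trials, path) {
  if (inherits(trials, "wcst_cohort")) trials <- trials$trials
  stopifnot(is.data.frame(trials))
  if (nrow(trials) > 0) {
    missing <- setdiff(TRIAL_LOG_COLUMNS, names(trials))
    if (length(missing))
      stopf("trial data lack column(s): %s",
            paste(missing, collapse = ", "))
    trials <- trials[order(trials$subject_id, trials$trial_index),
                     TRIAL_LOG_COLUMNS, drop = FALSE]
  } else {
    trials <- as.data.frame(
      stats::setNames(replicate(length(TRIAL_LOG_COLUMNS), logical(0),
                                simplify = FALSE), TRIAL_LOG_COLUMNS))
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(trials, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
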