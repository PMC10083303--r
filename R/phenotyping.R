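## From event logs to per-subject criterion scores, thresholds and
## addicted / non-addicted labels.

CRITERIA <- c("persistence", "motivation", "compulsivity")
SCORE_VARS <- c("persistence", "motivation", "compulsivity",
                "resistance_to_extinction", "drug_seeking",
                "impulsivity", "reward_sensitivity")

#' Summarize one session's event log
#'
#' Aggregates an [event_log()] into the per-session counts used by the
#' phenotyping layer. Timeout and drug-free poke counts are derived by
#' replaying the serialized event order (the timeout interval is half-open,
#' so a poke logged after `timeout_end` at the same timestamp is not a
#' timeout poke; this reproduces the engine's eligibility rules exactly).
#'
#' @param log An [event_log()].
#' @param config A [protocol_config()] (used for validation limits).
#' @return A one-row data.frame: `subject_id`, `session_id`,
#'   `session_kind`, `fr_value`, `active_pokes`, `inactive_pokes`,
#'   `reinforcers` (priming excluded), `timeout_active_pokes`,
#'   `drugfree_active_pokes`, `shocks`, `last_ratio_completed`,
#'   `duration_s`, `end_reason`.
#' @export
summarize_session <- function(log, config = default_protocol()) {
  validate_event_log(log, config)
  ev <- log$events
  ty <- ev$event_type
  in_to <- cumsum(ty == "timeout_start") - cumsum(ty == "timeout_end")
  in_df <- cumsum(ty == "drugfree_start") - cumsum(ty == "drugfree_end")
  act <- ty == "active_poke"
  end_meta <- parse_meta(ev$meta[length(ty)])
  last_ratio <- if ("last_ratio" %in% names(end_meta)) {
    as.integer(end_meta[["last_ratio"]])
  } else 0L
  fr_value <- if ("fr" %in% names(end_meta)) {
    as.integer(end_meta[["fr"]])
  } else NA_integer_
  data.frame(
    subject_id = log$subject_id,
    session_id = log$session_id,
    session_kind = log$session_kind,
    fr_value = fr_value,
    active_pokes = sum(act),
    inactive_pokes = sum(ty == "inactive_poke"),
    reinforcers = sum(ty == "infusion"),
    timeout_active_pokes = sum(act & in_to > 0L),
    drugfree_active_pokes = sum(act & in_df > 0L),
    shocks = sum(ty == "shock"),
    last_ratio_completed = last_ratio,
    duration_s = ev$t[length(ty)],
    end_reason = if ("reason" %in% names(end_meta)) end_meta[["reason"]] else "",
    stringsAsFactors = FALSE
  )
}

#' @rdname summarize_session
#' @param logs A list of `event_log`s in chronological order.
#' @return `summarize_sessions()`: one row per log, in the given order.
#' @export
summarize_sessions <- function(logs, config = default_protocol()) {
  do.call(rbind, lapply(logs, summarize_session, config = config))
}

#' Check the self-administration acquisition criteria
#'
#' A subject acquires the operant behavior when, over three consecutive
#' training sessions: (1) responding is stable, i.e. each day's reinforcer
#' count deviates from the 3-day mean by at most 20%; (2) at least 75% of
#' pooled responding is on the active hole; and (3) at least five
#' reinforcers are earned on every one of the three days.
#'
#' @param summaries Exactly three consecutive training-session summaries
#'   for one subject, as rows from [summarize_sessions()].
#' @return A list: `passed` plus the per-condition booleans and the
#'   quantities they were evaluated on (`max_rel_deviation`,
#'   `active_fraction`, `min_reinforcers`).
#' @export
check_acquisition <- function(summaries) {
  if (!is.data.frame(summaries) || nrow(summaries) != 3L) {
    stop("usage error: check_acquisition needs exactly 3 session summaries",
         call. = FALSE)
  }
  if (length(unique(summaries$subject_id)) != 1L) {
    stop("usage error: summaries must belong to one subject", call. = FALSE)
  }
  r <- summaries$reinforcers
  m <- mean(r)
  stability_ok <- m > 0 && max(abs(r - m)) / m <= 0.20
  act <- sum(summaries$active_pokes)
  inact <- sum(summaries$inactive_pokes)
  discrimination <- if (act + inact > 0) act / (act + inact) else 0
  discrimination_ok <- discrimination >= 0.75
  reinforcers_ok <- all(r >= 5)
  list(passed = stability_ok && discrimination_ok && reinforcers_ok,
       stability_ok = stability_ok,
       discrimination_ok = discrimination_ok,
       reinforcers_ok = reinforcers_ok,
       max_rel_deviation = if (m > 0) max(abs(r - m)) / m else NA_real_,
       active_fraction = discrimination,
       min_reinforcers = min(r))
}

#' Compute one subject's criterion scores, craving parameters and traits
#'
#' From all of a subject's session summaries (chronological order):
#' * `persistence` — mean drug-free active pokes over the three FR sessions
#'   immediately preceding the PR test;
#' * `motivation` — PR breaking point (last ratio completed);
#' * `compulsivity` — shock count in the shock session;
#' * `impulsivity` — mean timeout active pokes over the same three pre-PR
#'   sessions;
#' * `reward_sensitivity` — mean reinforcers over the last three FR2
#'   sessions before the PR;
#' * `resistance_to_extinction` — active pokes in the first extinction
#'   session (`NA` if extinction absent);
#' * `drug_seeking` — active pokes in the reinstatement session (`NA` if
#'   absent); the cue-phase count is not separated here but is available
#'   from the event log.
#'
#' @param summaries All session summaries of one subject, in chronological
#'   order (rows from [summarize_sessions()]).
#' @return One-row data.frame with `subject_id` and the seven scores.
#' @export
compute_scores <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1L)
  if (length(unique(summaries$subject_id)) != 1L) {
    stop("scoring error: summaries must belong to one subject", call. = FALSE)
  }
  kind <- summaries$session_kind
  pr_i <- which(kind == "PR")
  missing <- character(0)
  if (length(pr_i) < 1L) missing <- c(missing, "PR session")
  pre_fr <- if (length(pr_i)) which(kind == "FR" & seq_along(kind) < pr_i[1L]) else integer(0)
  if (length(pre_fr) < 3L) missing <- c(missing, ">= 3 FR sessions before PR")
  shock_i <- which(kind == "SHOCK")
  if (length(shock_i) < 1L) missing <- c(missing, "shock session")
  if (length(missing)) {
    stop("scoring error for subject ", summaries$subject_id[1L],
         ": missing ", paste(missing, collapse = "; "), call. = FALSE)
  }
  pre3 <- utils::tail(pre_fr, 3L)
  fr2 <- pre_fr[!is.na(summaries$fr_value[pre_fr]) &
                  summaries$fr_value[pre_fr] == 2L]
  fr2_3 <- if (length(fr2) >= 3L) utils::tail(fr2, 3L) else pre3
  ext_i <- which(kind == "EXTINCTION")
  reinst_i <- which(kind == "REINSTATEMENT")
  ## averaged scores are reported to 1e-6 so that serialized score tables
  ## classify identically to in-memory ones (ties at a threshold included)
  data.frame(
    subject_id = summaries$subject_id[1L],
    persistence = round(mean(summaries$drugfree_active_pokes[pre3]), 6),
    motivation = summaries$last_ratio_completed[pr_i[1L]],
    compulsivity = summaries$shocks[shock_i[1L]],
    impulsivity = round(mean(summaries$timeout_active_pokes[pre3]), 6),
    reward_sensitivity = round(mean(summaries$reinforcers[fr2_3]), 6),
    resistance_to_extinction = if (length(ext_i)) {
      summaries$active_pokes[ext_i[1L]]
    } else NA_real_,
    drug_seeking = if (length(reinst_i)) {
      summaries$active_pokes[reinst_i[1L]]
    } else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' 75th-percentile criterion thresholds from a reference group
#'
#' A subject is positive for an addiction-like criterion when its score is
#' equal to or beyond the 75th percentile of the reference distribution of
#' that criterion. The default percentile is the empirical quantile with
#' linear interpolation between order statistics (`stats::quantile`
#' type 7); `method = "normal"` instead uses the parametric
#' mean + z(0.75) * SD of a fitted normal.
#'
#' @param reference_scores data.frame of reference-group scores (as from
#'   [compute_scores()]).
#' @param criteria Score columns to threshold.
#' @param method `"empirical"` (type-7 quantile) or `"normal"`.
#' @return Named numeric vector of thresholds, with the method and
#'   reference size as attributes.
#' @export
compute_thresholds <- function(reference_scores,
                               criteria = CRITERIA,
                               method = c("empirical", "normal")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(reference_scores),
            all(criteria %in% names(reference_scores)))
  n <- nrow(reference_scores)
  if (n < 1L) stop("reference group is empty", call. = FALSE)
  if (n < 4L) {
    warning("fewer than 4 reference subjects: 75th percentile is poorly resolved")
  }
  th <- vapply(criteria, function(cr) {
    x <- reference_scores[[cr]]
    if (anyNA(x)) stop("reference scores contain NA for ", cr, call. = FALSE)
    if (method == "empirical") {
      unname(stats::quantile(x, 0.75, type = 7))
    } else {
      mean(x) + stats::qnorm(0.75) * stats::sd(x)
    }
  }, numeric(1L))
  attr(th, "method") <- method
  attr(th, "n_reference") <- n
  th
}

#' Classify subjects by the 2-of-3 addiction-criteria rule
#'
#' A criterion flag is raised when the score is greater than or equal to
#' its threshold; subjects with 2 or 3 positive criteria are labeled
#' `addicted` (vulnerable), those with 0 or 1 `non_addicted` (resilient).
#'
#' @param scores data.frame with the criterion score columns.
#' @param thresholds Named thresholds from [compute_thresholds()].
#' @param criteria Criterion columns (default the three addiction criteria).
#' @return `scores` with added logical flag columns (`<criterion>_flag`),
#'   `n_criteria` and `label`; thresholds attached as attribute
#'   `thresholds`.
#' @export
classify_subjects <- function(scores, thresholds, criteria = CRITERIA) {
  stopifnot(is.data.frame(scores), all(criteria %in% names(scores)),
            all(criteria %in% names(thresholds)))
  out <- scores
  for (cr in criteria) {
    if (anyNA(scores[[cr]])) {
      stop("classification error: NA score for ", cr, call. = FALSE)
    }
    out[[paste0(cr, "_flag")]] <- scores[[cr]] >= thresholds[[cr]]
  }
  flags <- as.matrix(out[paste0(criteria, "_flag")])
  out$n_criteria <- as.integer(rowSums(flags))
  out$label <- ifelse(out$n_criteria >= 2L, "addicted", "non_addicted")
  attr(out, "thresholds") <- thresholds
  out
}

#' Extinction criterion
#'
#' The criterion is reached when responses on the active hole are below 35%
#' of the mean of the last three self-administration days for three
#' consecutive extinction sessions (strict inequality).
#'
#' @param baseline Numeric vector of 3 active-poke counts from the last
#'   three self-administration days (positive mean required).
#' @param extinction_counts Active pokes per extinction session, in order.
#' @param fraction Criterion fraction of baseline (default 0.35).
#' @return List: `reached` and `session_reached` (index of the third
#'   session of the first qualifying run, or `NA`).
#' @export
check_extinction <- function(baseline, extinction_counts, fraction = 0.35) {
  if (length(baseline) != 3L) {
    stop("usage error: baseline must have 3 values", call. = FALSE)
  }
  bm <- mean(baseline)
  if (!is.finite(bm) || bm <= 0) {
    stop("extinction criterion undefined: baseline mean is not positive",
         call. = FALSE)
  }
  cutoff <- fraction * bm
  below <- extinction_counts < cutoff
  if (length(below) >= 3L) {
    run3 <- below[-c(1L, 2L)] & below[-c(1L, length(below))] &
      below[-c(length(below) - 1L, length(below))]
    if (any(run3)) {
      return(list(reached = TRUE, session_reached = which(run3)[1L] + 2L,
                  cutoff = cutoff))
    }
  }
  list(reached = FALSE, session_reached = NA_integer_, cutoff = cutoff)
}

#' Write / read per-subject scores as CSV
#'
#' Serializes the scores-and-classification table with missing optional
#' fields written as empty strings (not zeros).
#'
#' @param scores data.frame as returned by [classify_subjects()] (plus an
#'   optional `group` column).
#' @param path File path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
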