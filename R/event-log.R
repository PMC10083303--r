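## Event-log container and CSV serialization.
##
## Tie-breaking precedence for events sharing a timestamp (fixed so that
## serialized logs replay identically to the live engine): session-phase
## events -- house_light_on/off, drugfree_start/end, cue_phase_start and
## timeout_end (the timeout interval is half-open [start, end), so a poke at
## exactly the end boundary is eligible and must appear after timeout_end) --
## come first, then pokes, then shock, then (priming_)infusion, then
## cue_on/cue_off, then timeout_start, and session_end always last.

EVENT_TYPES <- c("active_poke", "inactive_poke", "priming_infusion",
                 "infusion", "cue_on", "cue_off", "house_light_on",
                 "house_light_off", "timeout_start", "timeout_end", "shock",
                 "drugfree_start", "drugfree_end", "cue_phase_start",
                 "session_end")

EVENT_PRECEDENCE <- c(
  house_light_on = 0, house_light_off = 0, drugfree_start = 0,
  drugfree_end = 0, cue_phase_start = 0, timeout_end = 0,
  active_poke = 1, inactive_poke = 1,
  shock = 2,
  priming_infusion = 3, infusion = 3,
  cue_on = 4, cue_off = 4,
  timeout_start = 5,
  session_end = 6
)

SESSION_KINDS <- c("FR", "PR", "SHOCK", "EXTINCTION", "REINSTATEMENT")

#' Construct an event log
#'
#' An `event_log` records every event of one subject-session: pokes on both
#' holes (including those during timeouts and drug-free periods), priming
#' and contingent infusions, cue and house-light transitions, timeouts,
#' shocks, phase transitions and the terminal `session_end` event. Times are
#' seconds from session start, stored to millisecond precision.
#'
#' @param subject_id,session_id Identifiers (no commas).
#' @param session_kind One of `"FR"`, `"PR"`, `"SHOCK"`, `"EXTINCTION"`,
#'   `"REINSTATEMENT"`.
#' @param events A data.frame with columns `t` (numeric seconds),
#'   `event_type` (character) and `meta` (character, `;`-separated
#'   `key=value` pairs or `""`).
#' @return An object of class `event_log`.
#' @export
event_log <- function(subject_id, session_id, session_kind, events) {
  stopifnot(is.character(subject_id) || is.numeric(subject_id),
            length(subject_id) == 1L, length(session_id) == 1L)
  session_kind <- match.arg(session_kind, SESSION_KINDS)
  subject_id <- as.character(subject_id)
  session_id <- as.character(session_id)
  if (grepl(",", subject_id) || grepl(",", session_id)) {
    stop("identifiers must not contain commas", call. = FALSE)
  }
  events <- data.frame(t = as.numeric(events$t),
                       event_type = as.character(events$event_type),
                       meta = as.character(events$meta),
                       stringsAsFactors = FALSE)
  structure(list(subject_id = subject_id, session_id = session_id,
                 session_kind = session_kind, events = events),
            class = "event_log")
}

#' Validate the structural invariants of an event log
#'
#' Checks that events are time-sorted with ties ordered by the documented
#' event-type precedence, that exactly one `session_end` closes the log,
#' that every infusion is immediately followed (same timestamp) by `cue_on`
#' and a `timeout_start` whose `timeout_end` occurs exactly `timeout_s`
#' later unless the session ends first, that no infusion falls inside a
#' drug-free interval, and that FR logs respect the reinforcer cap.
#'
#' @param log An `event_log`.
#' @param config A `protocol_config` (for `timeout_s` and the cap).
#' @return `log`, invisibly; errors describing the first violation.
#' @export
validate_event_log <- function(log, config = default_protocol()) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  if (nrow(ev) == 0L) stop("event log has no events", call. = FALSE)
  bad <- setdiff(unique(ev$event_type), EVENT_TYPES)
  if (length(bad)) {
    stop("unknown event types: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(ev$t)) stop("events not sorted by t", call. = FALSE)
  prec <- EVENT_PRECEDENCE[ev$event_type]
  same_t <- which(diff(ev$t) == 0)
  if (any(prec[same_t + 1L] < prec[same_t])) {
    i <- same_t[which(prec[same_t + 1L] < prec[same_t])][1L] + 1L
    stop("tie precedence violated at row ", i, " (", ev$event_type[i], ")",
         call. = FALSE)
  }
  ends <- which(ev$event_type == "session_end")
  if (length(ends) != 1L || ends != nrow(ev)) {
    stop("log must contain exactly one session_end, last in the list",
         call. = FALSE)
  }
  inf <- which(ev$event_type == "infusion")
  for (i in inf) {
    if (i + 2L > nrow(ev) ||
        ev$event_type[i + 1L] != "cue_on" || ev$t[i + 1L] != ev$t[i]) {
      stop("infusion at row ", i, " not immediately followed by cue_on",
           call. = FALSE)
    }
    j <- i + 1L
    while (j <= nrow(ev) && ev$t[j] == ev$t[i] &&
           ev$event_type[j] != "timeout_start") j <- j + 1L
    if (j > nrow(ev) || ev$t[j] != ev$t[i] ||
        ev$event_type[j] != "timeout_start") {
      stop("infusion at row ", i, " has no same-t timeout_start",
           call. = FALSE)
    }
    t_end <- ev$t[i] + config$timeout_s
    k <- which(ev$event_type == "timeout_end" & abs(ev$t - t_end) < 5e-4)
    if (length(k) == 0L && ev$t[nrow(ev)] >= t_end) {
      stop("timeout started at t=", ev$t[i], " has no timeout_end at +",
           config$timeout_s, " s", call. = FALSE)
    }
  }
  df_start <- ev$t[ev$event_type == "drugfree_start"]
  df_end <- ev$t[ev$event_type == "drugfree_end"]
  for (i in inf) {
    t <- ev$t[i]
    k <- findInterval(t, df_start)
    if (k >= 1L && (k > length(df_end) || t < df_end[k]) && t > df_start[k]) {
      stop("infusion at t=", t, " inside a drug-free interval", call. = FALSE)
    }
    if (k >= 1L && t == df_start[k]) {
      stop("infusion at t=", t, " at drug-free start", call. = FALSE)
    }
  }
  if (log$session_kind == "FR" && length(inf) > config$max_reinforcers) {
    stop("FR log exceeds max_reinforcers", call. = FALSE)
  }
  invisible(log)
}

fmt_t <- function(t) sprintf("%.3f", t)

#' Write / read an event log as CSV
#'
#' One file per subject-session with header
#' `subject_id,session_id,session_kind,t_s,event_type,meta`; times are
#' serialized with three decimal places, `meta` is a `;`-separated
#' `key=value` string, UTF-8 with LF line endings. Writing a log read from
#' disk reproduces the file byte for byte.
#'
#' @param log An `event_log`.
#' @param path File path.
#' @return `write_event_log()` returns `path` invisibly;
#'   `read_event_log()` returns an `event_log`.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  lines <- c("subject_id,session_id,session_kind,t_s,event_type,meta",
             sprintf("%s,%s,%s,%s,%s,%s", log$subject_id, log$session_id,
                     log$session_kind, fmt_t(ev$t), ev$event_type, ev$meta))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  d <- utils::read.csv(path, colClasses = c("character", "character",
                                            "character", "character",
                                            "character", "character"),
                       na.strings = NULL)
  need <- c("subject_id", "session_id", "session_kind", "t_s", "event_type",
            "meta")
  if (!identical(names(d), need)) {
    stop("parse error in ", path, ": expected header ",
         paste(need, collapse = ","), call. = FALSE)
  }
  if (nrow(d) == 0L) stop("parse error in ", path, ": no events", call. = FALSE)
  t <- suppressWarnings(as.numeric(d$t_s))
  if (anyNA(t)) {
    stop("parse error in ", path, " row ", which(is.na(t))[1L],
         ": unparseable t_s", call. = FALSE)
  }
  bad <- which(!(d$event_type %in% EVENT_TYPES))
  if (length(bad)) {
    stop("parse error in ", path, " row ", bad[1L], ": unknown event_type '",
         d$event_type[bad[1L]], "'", call. = FALSE)
  }
  if (length(unique(d$subject_id)) != 1L || length(unique(d$session_id)) != 1L ||
      length(unique(d$session_kind)) != 1L) {
    stop("parse error in ", path, ": mixed subject/session identifiers",
         call. = FALSE)
  }
  event_log(d$subject_id[1L], d$session_id[1L], d$session_kind[1L],
            data.frame(t = t, event_type = d$event_type, meta = d$meta,
                       stringsAsFactors = FALSE))
}

## Parse one ";"-separated "key=value" meta string into a named character
## vector (zero-length for "").
parse_meta <- function(meta) {
  if (is.na(meta) || !nzchar(meta)) return(character(0))
  parts <- strsplit(meta, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) if (length(x) > 1L) x[2L] else "",
                         character(1L)),
                  vapply(kv, `[`, character(1L), 1L))
}

#' @export
print.event_log <- function(x, ...) {
  n <- nrow(x$events)
  cat(sprintf("<event_log> %s / %s [%s]: %d events, %.1f s\n",
              x$subject_id, x$session_id, x$session_kind, n,
              x$events$t[n]))
  tab <- table(x$events$event_type)
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
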