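## Discrete-event engine for operant self-administration sessions.
##
## The engine advances continuous session time (seconds, committed to
## millisecond precision) by interleaving agent-proposed nose-pokes with
## scheduled transitions (house light, drug-free period, timeout ends, the
## reinstatement cue phase, and the session-ending rules). Agents are polled
## for their next action; whenever a scheduled transition occurs strictly
## before the proposed poke the transition is applied and the agent is
## re-polled, so stochastic agents with phase-dependent hazards behave as
## piecewise-exponential renewal processes (re-drawing an exponential wait
## at a phase change is distributionally exact by memorylessness).
## Transitions falling exactly on the proposed poke time are applied first
## and the poke is then committed at the same timestamp, except session end,
## which discards the pending poke.

#' Agent interface
#'
#' An agent is a function `f(state, elapsed_s)` returning the subject's next
#' intended action, either as a numeric vector `c(wait, hole)` with `hole`
#' coded `0` = none, `1` = active, `2` = inactive, or as a list
#' `list(wait =, hole =)` with `hole` one of `"none"`, `"active"`,
#' `"inactive"`. `wait` is the time from `elapsed_s` until the poke and must
#' be strictly positive (use `Inf` with hole `none` to fall silent).
#'
#' The engine may poll the agent several times before a poke is committed:
#' every scheduled transition (timeout end, drug-free period start/end, cue
#' phase start) discards the pending action and re-polls, so agents must
#' always answer relative to the current `elapsed_s`. Scripted agents
#' therefore keep absolute poke times and return `next_time - elapsed_s`.
#'
#' `state` is an environment with fields `kind` (session kind),
#' `session_index`, `in_timeout`, `in_drugfree`, `in_cue_phase`, `shocks`,
#' `infusions`, and `ratio_required` (current PR requirement, `NA`
#' otherwise). It must be treated as read-only.
#'
#' @name agent_interface
NULL

as_action <- function(act) {
  if (is.numeric(act) && length(act) == 2L) return(act)
  if (is.list(act)) {
    hole <- switch(as.character(act$hole),
                   none = 0, active = 1, inactive = 2,
                   stop("agent returned unknown hole '", act$hole, "'",
                        call. = FALSE))
    return(c(as.numeric(act$wait), hole))
  }
  stop("agent must return c(wait, hole) or list(wait=, hole=)", call. = FALSE)
}

run_session_impl <- function(kind, config, agent, subject_id, session_id,
                             session_index = 1L,
                             fr_value = config$fr_value) {
  validate_protocol_config(config)
  if (!is.function(agent)) stop("agent must be a function", call. = FALSE)
  stopifnot(fr_value >= 1L)

  tout <- config$timeout_s
  cap <- switch(kind,
                FR = config$session_cap_s,
                PR = config$pr_cap_s,
                SHOCK = config$shock_session_s,
                EXTINCTION = config$extinction_session_s,
                REINSTATEMENT = config$reinstatement_total_s)
  has_drugfree <- kind == "FR"
  df_start_t <- config$active_period_s
  df_end_t <- df_start_t + config$drugfree_period_s
  cue_t <- if (kind == "REINSTATEMENT") {
    config$reinstatement_total_s - config$reinstatement_cue_phase_s
  } else Inf
  hl_off_t <- min(config$house_light_start_s, cap)
  series <- config$pr_ratio_series

  ## event buffer with doubling growth
  buf_n <- 0L
  buf_cap <- 512L
  ev_t <- numeric(buf_cap); ev_y <- character(buf_cap); ev_m <- character(buf_cap)
  add <- function(t, y, m = "") {
    if (buf_n == buf_cap) {
      buf_cap <<- buf_cap * 2L
      length(ev_t) <<- buf_cap; length(ev_y) <<- buf_cap; length(ev_m) <<- buf_cap
    }
    buf_n <<- buf_n + 1L
    ev_t[buf_n] <<- t; ev_y[buf_n] <<- y; ev_m[buf_n] <<- m
  }

  ## mutable session state (shared with the agent, read-only by contract)
  st <- new.env(parent = emptyenv())
  st$kind <- kind
  st$session_index <- as.integer(session_index)
  st$in_timeout <- FALSE
  st$in_drugfree <- FALSE
  st$in_cue_phase <- FALSE
  st$shocks <- 0L
  st$infusions <- 0L
  st$ratio_required <- if (kind == "PR") series[1L] else NA_integer_

  timeout_end_t <- Inf
  hl_on <- TRUE
  df_started <- FALSE; df_ended <- FALSE; cue_started <- FALSE
  fr_count <- 0L
  pr_k <- 1L; pr_count <- 0L; last_ratio <- 0L
  last_poke_t <- 0
  shock_step <- 0L; shock_window_t <- Inf
  ended <- FALSE; end_reason <- ""
  ## pokes are committed at millisecond resolution and strictly after any
  ## reinforcement events (shock/infusion/cue/timeout_start) already logged
  ## at the current millisecond, keeping tie precedence self-consistent
  min_poke_t <- 0

  add(0, "house_light_on")
  if (kind == "FR") add(0, "priming_infusion", "noncontingent=1")

  infusion_chain <- function(t, meta = "") {
    add(t, "infusion", meta)
    add(t, "cue_on")
    add(t, "cue_off")      # cue light is off during the timeout
    add(t, "timeout_start")
    st$infusions <- st$infusions + 1L
    st$in_timeout <- TRUE
    timeout_end_t <<- t + tout
    min_poke_t <<- t + 0.001
  }

  end_session <- function(t, reason) {
    meta <- switch(kind,
      FR = sprintf("reason=%s;fr=%d;reinforcers=%d", reason, fr_value,
                   st$infusions),
      PR = sprintf("reason=%s;last_ratio=%d", reason, last_ratio),
      SHOCK = sprintf("reason=%s;shocks=%d;infusions=%d", reason, st$shocks,
                      st$infusions),
      sprintf("reason=%s", reason))
    add(t, "session_end", meta)
    ended <<- TRUE
  }

  ## next scheduled transition: c(time, code)
  ## codes: 1 house light off, 2 drug-free start, 3 drug-free end,
  ##        4 timeout end, 5 cue phase start, 6 session cap, 7 PR inactivity
  next_transition <- function() {
    bt <- cap; bc <- 6L
    if (kind == "PR") {
      it <- last_poke_t + config$pr_inactivity_s
      if (it < bt) { bt <- it; bc <- 7L }
    }
    if (hl_on && !st$in_drugfree && hl_off_t < bt) { bt <- hl_off_t; bc <- 1L }
    if (has_drugfree && !df_started && df_start_t < bt) { bt <- df_start_t; bc <- 2L }
    if (has_drugfree && df_started && !df_ended && df_end_t < bt) { bt <- df_end_t; bc <- 3L }
    if (st$in_timeout && timeout_end_t < bt) { bt <- timeout_end_t; bc <- 4L }
    if (!cue_started && cue_t < bt) { bt <- cue_t; bc <- 5L }
    c(bt, bc)
  }

  apply_transition <- function(tr) {
    t <- tr[1L]
    switch(tr[2L],
      { add(t, "house_light_off"); hl_on <<- FALSE },                   # 1
      { add(t, "drugfree_start"); add(t, "house_light_on")              # 2
        st$in_drugfree <- TRUE; df_started <<- TRUE; hl_on <<- TRUE },
      { add(t, "drugfree_end"); add(t, "house_light_off")               # 3
        st$in_drugfree <- FALSE; df_ended <<- TRUE; hl_on <<- FALSE },
      { add(t, "timeout_end"); st$in_timeout <- FALSE                   # 4
        timeout_end_t <<- Inf },
      { add(t, "cue_phase_start"); st$in_cue_phase <- TRUE              # 5
        cue_started <<- TRUE; fr_count <<- 0L },
      end_session(t, "cap"),                                            # 6
      end_session(t, "inactivity")                                      # 7
    )
  }

  t <- 0
  while (!ended) {
    act <- as_action(agent(st, t))
    w <- act[1L]; hole <- act[2L]
    if (is.na(w) || w <= 0) {
      stop("protocol error: agent returned non-positive wait at t=", t,
           call. = FALSE)
    }
    poke_t <- if (hole == 0 && !is.finite(w)) Inf else {
      max(round(t + w, 3), min_poke_t)
    }

    ## apply transitions up to (and at) the proposed poke time
    repoll <- FALSE
    repeat {
      tr <- next_transition()
      if (tr[1L] < poke_t) {
        t <- tr[1L]
        apply_transition(tr)
        if (ended) break
        repoll <- TRUE   # state changed before the poke: re-poll the agent
        break
      } else if (tr[1L] == poke_t) {
        t <- tr[1L]
        apply_transition(tr)   # transition first, poke still committed
        if (ended) break       # ...unless the session just ended
      } else break
    }
    if (ended) break
    if (repoll || hole == 0) { if (hole == 0 && !repoll) t <- poke_t; next }

    ## commit the poke
    t <- poke_t
    if (kind == "PR") last_poke_t <- t
    eligible <- !st$in_timeout && !st$in_drugfree
    if (hole == 1) {
      add(t, "active_poke")
      if (eligible) {
        if (kind == "FR") {
          fr_count <- fr_count + 1L
          if (fr_count == fr_value) {
            fr_count <- 0L
            infusion_chain(t)
            if (st$infusions >= config$max_reinforcers) {
              end_session(t, "reinforcer_cap")
            }
          }
        } else if (kind == "PR") {
          pr_count <- pr_count + 1L
          if (pr_count == series[pr_k]) {
            pr_count <- 0L
            last_ratio <- series[pr_k]
            infusion_chain(t, sprintf("ratio=%d", series[pr_k]))
            pr_k <- pr_k + 1L
            if (pr_k > length(series)) {
              end_session(t, "series_exhausted")
            } else {
              st$ratio_required <- series[pr_k]
            }
          }
        } else if (kind == "SHOCK") {
          if (shock_step == 1L && t > shock_window_t) shock_step <- 0L
          min_poke_t <- t + 0.001
          if (shock_step == 0L) {
            add(t, "shock", sprintf("mA=%.2f", config$shock_mA))
            st$shocks <- st$shocks + 1L
            shock_step <- 1L
            shock_window_t <- t + config$shock_pair_window_s
          } else {
            add(t, "shock", sprintf("mA=%.2f", config$shock_mA))
            st$shocks <- st$shocks + 1L
            infusion_chain(t)
            shock_step <- 0L
          }
        } else if (kind == "REINSTATEMENT" && st$in_cue_phase) {
          fr_count <- fr_count + 1L
          if (fr_count == 2L) {       # FR2 schedule, cues only, no drug
            fr_count <- 0L
            add(t, "cue_on")
            add(t, "cue_off")
            min_poke_t <- t + 0.001
          }
        }
        ## EXTINCTION: pokes recorded, contingency disabled
      }
    } else {
      add(t, "inactive_poke")
    }
  }

  event_log(subject_id, session_id, kind,
            data.frame(t = ev_t[seq_len(buf_n)],
                       event_type = ev_y[seq_len(buf_n)],
                       meta = ev_m[seq_len(buf_n)],
                       stringsAsFactors = FALSE))
}

#' Run a fixed-ratio (FR) self-administration session
#'
#' Simulates one daily FR session: a non-contingent priming infusion and
#' house light at t = 0 (light off after `house_light_start_s`), two active
#' periods separated by a drug-free period during which the house light is
#' on and pokes are recorded but never reinforced, one infusion (with cue
#' light and pump cues, followed by a timeout) per `fr_value`-th eligible
#' active poke, and termination at the reinforcer cap or the session cap,
#' whichever comes first. Pokes during timeouts and the drug-free period do
#' not advance the ratio counter.
#'
#' @param config A [protocol_config()].
#' @param agent An agent function (see [agent_interface]).
#' @param subject_id,session_id Identifiers for the log.
#' @param session_index Training-session counter passed through to the agent
#'   (drives acquisition learning in stochastic agents).
#' @param fr_value Fixed-ratio requirement for this session (defaults to
#'   `config$fr_value`).
#' @return An [event_log()].
#' @export
run_fr_session <- function(config, agent, subject_id = "S1",
                           session_id = "FR_1", session_index = 1L,
                           fr_value = config$fr_value) {
  run_session_impl("FR", config, agent, subject_id, session_id,
                   session_index, fr_value)
}

#' Run a progressive-ratio (PR) session
#'
#' The k-th infusion requires `config$pr_ratio_series[k]` eligible active
#' pokes since the previous infusion (timeout pokes excluded). The session
#' ends at the PR cap, when a full `pr_inactivity_s` passes without a poke
#' on either hole (sliding window), or when the ratio series is exhausted.
#' The last ratio completed (the breaking point) is recorded in the
#' `session_end` meta as `last_ratio`.
#'
#' @inheritParams run_fr_session
#' @return An [event_log()].
#' @export
run_pr_session <- function(config, agent, subject_id = "S1",
                           session_id = "PR_1", session_index = 1L) {
  run_session_impl("PR", config, agent, subject_id, session_id, session_index)
}

#' Run a foot-shock punishment (compulsivity) session
#'
#' A two-step FR2 cycle: the first eligible active poke triggers a
#' foot-shock; a second eligible active poke within
#' `shock_pair_window_s` triggers a shock paired with the drug infusion and
#' cue (followed by a timeout). If the window lapses the cycle resets, and
#' the late poke counts as a new first step. Runs for `shock_session_s`
#' with no drug-free period; the shock count is recorded in the
#' `session_end` meta.
#'
#' @inheritParams run_fr_session
#' @return An [event_log()].
#' @export
run_shock_session <- function(config, agent, subject_id = "S1",
                              session_id = "SHOCK_1", session_index = 1L) {
  run_session_impl("SHOCK", config, agent, subject_id, session_id,
                   session_index)
}

#' Run an extinction session
#'
#' No priming, no infusions and no cues are ever delivered; all pokes are
#' recorded. The session ends at `extinction_session_s`.
#'
#' @inheritParams run_fr_session
#' @return An [event_log()].
#' @export
run_extinction_session <- function(config, agent, subject_id = "S1",
                                   session_id = "EXT_1", session_index = 1L) {
  run_session_impl("EXTINCTION", config, agent, subject_id, session_id,
                   session_index)
}

#' Run a cue-induced reinstatement session
#'
#' Before `cue_phase_start` (at `reinstatement_total_s -
#' reinstatement_cue_phase_s`) the session behaves like extinction. From the
#' cue phase on, every completed FR2 on the active hole yields the
#' environmental cues (cue on/off) but never an infusion. The session ends
#' at `reinstatement_total_s`.
#'
#' @inheritParams run_fr_session
#' @return An [event_log()].
#' @export
run_reinstatement_session <- function(config, agent, subject_id = "S1",
                                      session_id = "REINST_1",
                                      session_index = 1L) {
  run_session_impl("REINSTATEMENT", config, agent, subject_id, session_id,
                   session_index)
}
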