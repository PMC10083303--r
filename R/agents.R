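## Agents: deterministic scripted pokers for protocol verification, and the
## stochastic latent-trait agent that generates synthetic cohorts.

#' Scripted and periodic agents
#'
#' `scripted_agent()` pokes at the given absolute session times (strictly
#' increasing, seconds); `periodic_agent()` pokes every `interval` seconds
#' starting at `start`. Both satisfy the engine's re-polling contract (see
#' [agent_interface]) and fall silent once their schedule is exhausted.
#'
#' @param times Strictly increasing numeric vector of poke times (s).
#' @param hole `"active"` or `"inactive"`.
#' @return An agent function.
#' @export
scripted_agent <- function(times, hole = c("active", "inactive")) {
  hole_code <- if (match.arg(hole) == "active") 1 else 2
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0)) {
    stop("scripted times must be strictly increasing", call. = FALSE)
  }
  i <- 1L
  n <- length(times)
  function(state, elapsed_s) {
    while (i <= n && times[i] <= elapsed_s) i <<- i + 1L
    if (i > n) return(c(Inf, 0))
    c(times[i] - elapsed_s, hole_code)
  }
}

#' @rdname scripted_agent
#' @param interval Seconds between pokes.
#' @param start Time of the first poke (s).
#' @param until Stop poking after this session time (s).
#' @export
periodic_agent <- function(interval, hole = c("active", "inactive"),
                           start = interval, until = Inf) {
  hole_code <- if (match.arg(hole) == "active") 1 else 2
  stopifnot(interval > 0, start > 0)
  nxt <- start
  function(state, elapsed_s) {
    while (nxt <= elapsed_s) nxt <<- nxt + interval
    if (nxt > until) return(c(Inf, 0))
    c(nxt - elapsed_s, hole_code)
  }
}

#' Stochastic latent-trait agent
#'
#' Builds the behavioral agent of the synthetic-cohort model from one
#' subject's trait profile. Nose-pokes arise from a renewal process with
#' exponential (memoryless) inter-poke intervals whose hazard is the
#' product of a base rate (pokes/min, converted to per-second) and
#' phase-dependent multipliers:
#'
#' * acquisition learning: the active-hole rate in FR training session
#'   \eqn{s} is scaled by \eqn{A - (A - 1) e^{-(s-1)/2}}, a saturating
#'   approach from 1 to the asymptote \eqn{A} (`learning_gain`); PR, shock,
#'   extinction and reinstatement sessions use the asymptote;
#' * `impulsivity` multiplies the active hazard during timeouts;
#' * `perseverance` multiplies the active hazard during the drug-free
#'   period;
#' * in extinction session \eqn{s}, the active hazard is scaled by
#'   \eqn{e^{-\delta (s-1)}} (`extinction_decay`), times `burst_gain` in the
#'   first session (the extinction burst); the reinstatement session
#'   continues the decay and applies `cue_gain` during the cue phase;
#' * in a PR session, the agent stops responding entirely once the required
#'   ratio exceeds its give-up threshold `motivation`;
#' * in the shock session, after each shock the agent keeps responding with
#'   probability `shock_tolerance`, otherwise it falls permanently silent.
#'
#' The hole is chosen active vs inactive with probability proportional to
#' the two hazards; the inactive hazard is the constant
#' `base_inactive_rate`. A fresh agent must be created for every session
#' (it carries within-session memory of the shock-quit state).
#'
#' @param profile One row of a [sample_cohort()] data frame (or any list
#'   with the trait fields).
#' @return An agent function for the session engine.
#' @seealso [sample_cohort()], [agent_interface]
#' @export
trait_agent <- function(profile) {
  ra <- profile$base_active_rate / 60
  ri <- profile$base_inactive_rate / 60
  A <- profile$learning_gain
  iota <- profile$impulsivity
  persev <- profile$perseverance
  mu <- profile$motivation
  kappa <- profile$shock_tolerance
  delta <- profile$extinction_decay
  burst <- profile$burst_gain
  cueg <- profile$cue_gain
  stopifnot(ra >= 0, ri >= 0, A >= 1, iota >= 0, persev >= 0,
            kappa >= 0, kappa <= 1, delta >= 0, burst >= 1, cueg >= 1)

  shocks_seen <- 0L
  quit <- FALSE

  function(state, elapsed_s) {
    kind <- state$kind
    m <- 1
    if (kind == "FR") {
      s <- state$session_index
      m <- A - (A - 1) * exp(-(s - 1) / 2)
      if (state$in_drugfree) m <- m * persev
    } else if (kind == "PR") {
      m <- A
      if (!is.na(state$ratio_required) && state$ratio_required > mu) {
        return(c(Inf, 0))   # give-up threshold exceeded
      }
    } else if (kind == "SHOCK") {
      if (state$shocks > shocks_seen) {
        new <- state$shocks - shocks_seen
        shocks_seen <<- state$shocks
        if (any(stats::runif(new) > kappa)) quit <<- TRUE
      }
      if (quit) return(c(Inf, 0))
      m <- A
    } else if (kind == "EXTINCTION") {
      s <- state$session_index
      m <- A * exp(-delta * (s - 1)) * (if (s == 1L) burst else 1)
    } else if (kind == "REINSTATEMENT") {
      s <- state$session_index
      m <- A * exp(-delta * (s - 1))
      if (state$in_cue_phase) m <- m * cueg
    }
    if (state$in_timeout) m <- m * iota
    la <- ra * m
    tot <- la + ri
    if (tot <= 0) return(c(Inf, 0))
    w <- stats::rexp(1L, tot)
    hole <- if (stats::runif(1L) < la / tot) 1 else 2
    c(w, hole)
  }
}
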