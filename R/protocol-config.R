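#' Progressive-ratio response requirement series
#'
#' The escalating series of active-hole responses required per infusion in
#' the progressive-ratio (PR) session. The breaking point is the last ratio
#' of this series a subject completes.
#'
#' @return Integer vector of 35 strictly increasing ratio requirements.
#' @export
pr_ratio_series <- function() {
  c(1L, 5L, 12L, 21L, 33L, 51L, 75L, 90L, 120L, 155L, 180L, 225L, 260L,
    300L, 350L, 410L, 465L, 540L, 630L, 730L, 850L, 1000L, 1200L, 1500L,
    1800L, 2100L, 2400L, 2700L, 3000L, 3400L, 3800L, 4200L, 4600L, 5000L,
    5500L)
}

#' Protocol configuration for operant self-administration sessions
#'
#' Bundles every timing and contingency parameter of the self-administration
#' protocol. Defaults reproduce the standard mouse protocol: daily sessions
#' of two 55-min active periods separated by a 15-min drug-free period
#' (125 min total), a 10-s post-infusion timeout, a 50-reinforcer cap,
#' a 4-h PR session ended early after 1 h without any nose-poke, a 50-min
#' shock test with a 1-min pairing window, ten 2-h extinction sessions and a
#' 90-min reinstatement session whose last 30 min are the cue phase.
#'
#' @param fr_value Fixed-ratio requirement (1 or 2).
#' @param n_fr1_sessions,n_fr2_sessions Number of FR1 / FR2 training sessions.
#' @param active_period_s Duration of each of the two active periods (s).
#' @param drugfree_period_s Duration of the mid-session drug-free period (s).
#' @param timeout_s Post-infusion timeout (s); pokes during it are recorded
#'   but never reinforced and do not advance the ratio counter.
#' @param max_reinforcers Reinforcer cap per FR session.
#' @param session_cap_s Total FR session duration (s).
#' @param pr_ratio_series Integer vector of PR response requirements.
#' @param pr_cap_s Maximum PR session duration (s).
#' @param pr_inactivity_s PR ends when no poke on either hole occurred for
#'   this long (s); sliding window.
#' @param shock_session_s Duration of the shock (punishment) test (s).
#' @param shock_pair_window_s Window to complete the second response of the
#'   shock FR2 cycle before it resets (s).
#' @param shock_mA Foot-shock current in mA (metadata only).
#' @param extinction_session_s Duration of each extinction session (s).
#' @param n_extinction_sessions Number of extinction sessions.
#' @param reinstatement_total_s Total reinstatement session duration (s).
#' @param reinstatement_cue_phase_s Duration of the terminal cue phase (s).
#' @param house_light_start_s House light stays on for this long at session
#'   start (s).
#'
#' @return An object of class `protocol_config` (a named list).
#' @seealso [default_protocol()], [read_protocol_config()]
#' @export
protocol_config <- function(fr_value = 1L,
                            n_fr1_sessions = 5L,
                            n_fr2_sessions = 5L,
                            active_period_s = 3300,
                            drugfree_period_s = 900,
                            timeout_s = 10,
                            max_reinforcers = 50L,
                            session_cap_s = 2 * active_period_s + drugfree_period_s,
                            pr_ratio_series = operantSA::pr_ratio_series(),
                            pr_cap_s = 14400,
                            pr_inactivity_s = 3600,
                            shock_session_s = 3000,
                            shock_pair_window_s = 60,
                            shock_mA = 0.18,
                            extinction_session_s = 7200,
                            n_extinction_sessions = 10L,
                            reinstatement_total_s = 5400,
                            reinstatement_cue_phase_s = 1800,
                            house_light_start_s = 3) {
  cfg <- list(
    fr_value = as.integer(fr_value),
    n_fr1_sessions = as.integer(n_fr1_sessions),
    n_fr2_sessions = as.integer(n_fr2_sessions),
    active_period_s = as.numeric(active_period_s),
    drugfree_period_s = as.numeric(drugfree_period_s),
    timeout_s = as.numeric(timeout_s),
    max_reinforcers = as.integer(max_reinforcers),
    session_cap_s = as.numeric(session_cap_s),
    pr_ratio_series = as.integer(pr_ratio_series),
    pr_cap_s = as.numeric(pr_cap_s),
    pr_inactivity_s = as.numeric(pr_inactivity_s),
    shock_session_s = as.numeric(shock_session_s),
    shock_pair_window_s = as.numeric(shock_pair_window_s),
    shock_mA = as.numeric(shock_mA),
    extinction_session_s = as.numeric(extinction_session_s),
    n_extinction_sessions = as.integer(n_extinction_sessions),
    reinstatement_total_s = as.numeric(reinstatement_total_s),
    reinstatement_cue_phase_s = as.numeric(reinstatement_cue_phase_s),
    house_light_start_s = as.numeric(house_light_start_s)
  )
  class(cfg) <- "protocol_config"
  validate_protocol_config(cfg)
  cfg
}

#' Default protocol configuration
#'
#' @return A `protocol_config` with all defaults.
#' @export
default_protocol <- function() protocol_config()

#' Validate a protocol configuration
#'
#' Checks positivity and the structural invariants of the protocol: the PR
#' series must be strictly increasing with first element >= 1, and the cue
#' phase must be shorter than the reinstatement session.
#'
#' @param config A `protocol_config`.
#' @return `config`, invisibly; errors on violation.
#' @export
validate_protocol_config <- function(config) {
  stopifnot(inherits(config, "protocol_config"))
  if (!(config$fr_value %in% c(1L, 2L))) {
    stop("config error: fr_value must be 1 or 2", call. = FALSE)
  }
  if (config$active_period_s <= 0) {
    stop("config error: active_period_s must be positive", call. = FALSE)
  }
  pos <- c("drugfree_period_s", "timeout_s", "session_cap_s", "pr_cap_s",
           "pr_inactivity_s", "shock_session_s", "shock_pair_window_s",
           "extinction_session_s", "reinstatement_total_s",
           "reinstatement_cue_phase_s")
  for (f in pos) {
    if (!is.finite(config[[f]]) || config[[f]] <= 0) {
      stop("config error: ", f, " must be positive and finite", call. = FALSE)
    }
  }
  s <- config$pr_ratio_series
  if (length(s) < 1L || s[1L] < 1L || any(diff(s) <= 0L)) {
    stop("config error: pr_ratio_series must be strictly increasing with first element >= 1",
         call. = FALSE)
  }
  if (config$reinstatement_cue_phase_s >= config$reinstatement_total_s) {
    stop("config error: reinstatement_cue_phase_s must be < reinstatement_total_s",
         call. = FALSE)
  }
  if (config$max_reinforcers < 1L) {
    stop("config error: max_reinforcers must be >= 1", call. = FALSE)
  }
  invisible(config)
}

#' Read / write a protocol configuration as YAML
#'
#' The YAML file mirrors the `protocol_config` field names. A defaults file
#' with the standard protocol ships in
#' `system.file("extdata", "protocol_default.yaml", package = "operantSA")`.
#'
#' @param path File path.
#' @return `read_protocol_config()` returns a validated `protocol_config`;
#'   `write_protocol_config()` returns `path` invisibly.
#' @export
read_protocol_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(protocol_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("config error: unknown protocol keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(protocol_config, vals)
}

#' @rdname read_protocol_config
#' @param config A `protocol_config`.
#' @export
write_protocol_config <- function(config, path) {
  validate_protocol_config(config)
  x <- unclass(config)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("<protocol_config>\n")
  cat(sprintf("  FR%d training, %d + %d sessions; session cap %.0f s (%d reinforcers max)\n",
              x$fr_value, x$n_fr1_sessions, x$n_fr2_sessions,
              x$session_cap_s, x$max_reinforcers))
  cat(sprintf("  active 2 x %.0f s, drug-free %.0f s, timeout %.0f s\n",
              x$active_period_s, x$drugfree_period_s, x$timeout_s))
  cat(sprintf("  PR: %d ratios (%d..%d), cap %.0f s, inactivity stop %.0f s\n",
              length(x$pr_ratio_series), x$pr_ratio_series[1],
              max(x$pr_ratio_series), x$pr_cap_s, x$pr_inactivity_s))
  cat(sprintf("  shock test %.0f s (window %.0f s, %.2f mA); extinction %d x %.0f s; reinstatement %.0f s (cue phase last %.0f s)\n",
              x$shock_session_s, x$shock_pair_window_s, x$shock_mA,
              x$n_extinction_sessions, x$extinction_session_s,
              x$reinstatement_total_s, x$reinstatement_cue_phase_s))
  invisible(x)
}
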