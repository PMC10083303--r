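# Shared fixtures and cached heavy computations.

.sweep_cache <- new.env(parent = emptyenv())

# Simulate the default cohort through the criteria stages (FR1 x5, FR2 x5,
# PR, FR2 stabilizer, shock) and phenotype it, for a block of seeds.
# Cached so the recovery acceptance check and the phenotyping invariants
# share one sweep.
recovery_sweep <- function(n_seeds = 20L, n_subjects = 60L) {
  key <- sprintf("sweep_%d_%d", n_seeds, n_subjects)
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  out <- lapply(seq_len(n_seeds), function(s) {
    sim <- simulate_experiment(
      cohort_spec(n_subjects = n_subjects, seed = 1000L + s),
      stages = c("fr1", "fr2", "pr", "stabilizer", "shock"))
    ph <- phenotype_cohort(sim$logs, cohort = sim$cohort,
                           reference_group = "saline")
    sc <- ph$scores
    truth <- sim$cohort$ground_truth_label[
      match(sc$subject_id, sim$cohort$subject_id)]
    ref <- sc$group == "saline"
    list(
      sensitivity = mean(sc$label[truth == "vulnerable"] == "addicted"),
      specificity = mean(sc$label[truth == "resilient"] == "non_addicted"),
      ref_positive = c(
        persistence = mean(sc$persistence_flag[ref]),
        motivation = mean(sc$motivation_flag[ref]),
        compulsivity = mean(sc$compulsivity_flag[ref])),
      n_included = nrow(sc),
      n_excluded = nrow(ph$exclusions))
  })
  .sweep_cache[[key]] <- out
  out
}

# Minimal meta-string parser (independent of the package internals).
parse_meta_test <- function(m) {
  kv <- strsplit(strsplit(m, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

# An agent that never responds.
silent_agent <- function() function(state, elapsed_s) c(Inf, 0)

# A one-row session summary for acquisition/scoring tests.
mk_summary <- function(subject_id = "S1", session_id = "FR2_01",
                       session_kind = "FR", fr_value = 2L,
                       active = 0L, inactive = 0L, reinforcers = 0L,
                       timeout_active = 0L, drugfree_active = 0L,
                       shocks = 0L, last_ratio = 0L, duration = 7500) {
  data.frame(subject_id = subject_id, session_id = session_id,
             session_kind = session_kind, fr_value = fr_value,
             active_pokes = active, inactive_pokes = inactive,
             reinforcers = reinforcers, timeout_active_pokes = timeout_active,
             drugfree_active_pokes = drugfree_active, shocks = shocks,
             last_ratio_completed = last_ratio, duration_s = duration,
             end_reason = "cap", stringsAsFactors = FALSE)
}

# Independent replay oracle: re-derive FR infusion times from the poke
# stream and the printed contingency rules alone (fr-th eligible active
# poke outside timeouts and the drug-free period, capped reinforcers).
replay_fr_infusions <- function(log, config, fr_value) {
  ev <- log$events
  pokes <- ev$t[ev$event_type == "active_poke"]
  df0 <- config$active_period_s
  df1 <- df0 + config$drugfree_period_s
  inf_t <- numeric(0)
  cnt <- 0L
  to_end <- -Inf
  for (tp in pokes) {
    if (tp >= df0 && tp < df1) next        # drug-free period
    if (tp < to_end) next                  # timeout
    cnt <- cnt + 1L
    if (cnt == fr_value) {
      cnt <- 0L
      inf_t <- c(inf_t, tp)
      to_end <- tp + config$timeout_s
      if (length(inf_t) == config$max_reinforcers) break
    }
  }
  inf_t
}
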