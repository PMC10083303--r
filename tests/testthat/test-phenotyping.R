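cfg <- default_protocol()

test_that("session summaries count pokes by phase from the event stream", {
  # empty-response session: all counts zero
  s0 <- summarize_session(run_fr_session(cfg, silent_agent()), cfg)
  expect_equal(s0$active_pokes, 0L)
  expect_equal(s0$inactive_pokes, 0L)
  expect_equal(s0$reinforcers, 0L)
  expect_equal(s0$timeout_active_pokes, 0L)
  expect_equal(s0$drugfree_active_pokes, 0L)

  # 12 well-spaced FR1 pokes -> 12 reinforcers (replay-derived)
  log <- run_fr_session(cfg, scripted_agent(seq(60, by = 60, length.out = 12)),
                        fr_value = 1L)
  s <- summarize_session(log, cfg)
  expect_equal(s$reinforcers, 12L)
  expect_equal(length(replay_fr_infusions(log, cfg, 1L)), 12L)

  # PR meta carries the breaking point into the summary
  pr <- run_pr_session(cfg, scripted_agent(seq(20, by = 20, length.out = 72)))
  expect_equal(summarize_session(pr, cfg)$last_ratio_completed, 33L)
})

test_that("acquisition requires stability, discrimination and 5 reinforcers", {
  mk3 <- function(r, act, inact) {
    do.call(rbind, lapply(1:3, function(i) {
      mk_summary(session_id = sprintf("FR2_%02d", i), reinforcers = r[i],
                 active = act[i], inactive = inact[i])
    }))
  }
  # perfectly stable, well discriminated
  res <- check_acquisition(mk3(c(10, 10, 10), c(10, 10, 10), c(2, 2, 1)))
  expect_true(res$passed)

  # (10,13,10): max deviation 2/11 = 18.2% <= 20% -> stability holds
  res2 <- check_acquisition(mk3(c(10, 13, 10), c(30, 30, 30), c(3, 3, 3)))
  expect_true(res2$stability_ok)
  expect_equal(res2$max_rel_deviation, 2 / 11, tolerance = 1e-12)

  # (10,16,10): deviation 4/12 = 33% -> stability fails
  expect_false(check_acquisition(mk3(c(10, 16, 10), c(30, 30, 30),
                                     c(3, 3, 3)))$stability_ok)

  # a day under 5 reinforcers fails regardless of stability
  res3 <- check_acquisition(mk3(c(10, 10, 4), c(30, 30, 30), c(1, 1, 1)))
  expect_false(res3$passed)
  expect_false(res3$reinforcers_ok)

  # discrimination is pooled over the three days; exactly 75% passes (>=)
  res4 <- check_acquisition(mk3(c(10, 10, 10), c(30, 30, 30), c(10, 10, 10)))
  expect_true(res4$passed)
  expect_equal(res4$active_fraction, 0.75, tolerance = 1e-12)
  res5 <- check_acquisition(mk3(c(10, 10, 10), c(29, 30, 30), c(10, 10, 10)))
  expect_false(res5$discrimination_ok)
  expect_false(res5$passed)

  expect_error(check_acquisition(mk3(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0))[1:2, ]),
               "exactly 3")
})

test_that("criterion scores aggregate the prescribed sessions", {
  rows <- rbind(
    mk_summary(session_id = "FR1_01", fr_value = 1L, drugfree_active = 100,
               timeout_active = 100, reinforcers = 30),
    mk_summary(session_id = "FR2_01", drugfree_active = 2, timeout_active = 1,
               reinforcers = 20),
    mk_summary(session_id = "FR2_02", drugfree_active = 6, timeout_active = 3,
               reinforcers = 30),
    mk_summary(session_id = "FR2_03", drugfree_active = 7, timeout_active = 4,
               reinforcers = 40),
    mk_summary(session_id = "FR2_04", drugfree_active = 8, timeout_active = 5,
               reinforcers = 50),
    mk_summary(session_id = "PR_01", session_kind = "PR", fr_value = NA,
               last_ratio = 5500L, duration = 14400),
    mk_summary(session_id = "FR2_05", drugfree_active = 50, timeout_active = 50,
               reinforcers = 10),
    mk_summary(session_id = "SHOCK_01", session_kind = "SHOCK", fr_value = NA,
               shocks = 6L, duration = 3000),
    mk_summary(session_id = "EXT_01", session_kind = "EXTINCTION",
               fr_value = NA, active = 120, duration = 7200),
    mk_summary(session_id = "REINST_01", session_kind = "REINSTATEMENT",
               fr_value = NA, active = 64, duration = 5400)
  )
  sc <- compute_scores(rows)
  # means over the three FR sessions immediately before the PR (FR2_02..04)
  expect_equal(sc$persistence, 7)
  expect_equal(sc$impulsivity, 4)
  expect_equal(sc$reward_sensitivity, 40)
  expect_equal(sc$motivation, 5500L)   # top of the printed series
  expect_equal(sc$compulsivity, 6L)
  expect_equal(sc$resistance_to_extinction, 120)
  expect_equal(sc$drug_seeking, 64)

  # craving fields are absent (NA), not zero, when those sessions are missing
  sc2 <- compute_scores(rows[1:8, ])
  expect_true(is.na(sc2$resistance_to_extinction))
  expect_true(is.na(sc2$drug_seeking))

  # missing mandatory sessions are a scoring error naming the gap
  expect_error(compute_scores(rows[c(1:5, 7), ]), "PR session")
  expect_error(compute_scores(rows[c(1:2, 6, 8), ]), "3 FR sessions")
  expect_error(compute_scores(rows[1:6, ]), "shock")
})

test_that("75th-percentile thresholds follow the type-7 convention", {
  ref <- data.frame(persistence = c(1, 2, 3, 4), motivation = c(0, 0, 0, 0),
                    compulsivity = c(2, 4, 6, 8))
  th <- compute_thresholds(ref)
  expect_equal(unname(th["persistence"]), 3.25)
  expect_equal(unname(th["motivation"]), 0)
  expect_equal(unname(th["compulsivity"]), 6.5)

  # degenerate all-zero reference: threshold 0 and a 0 score is positive
  cl <- classify_subjects(
    data.frame(subject_id = "a", persistence = 0, motivation = 0,
               compulsivity = 0),
    c(persistence = 0, motivation = 0, compulsivity = 0))
  expect_equal(cl$n_criteria, 3L)
  expect_equal(cl$label, "addicted")

  # brute-force percentile oracle on random reference vectors
  q75_brute <- function(x) {
    xs <- sort(x)
    h <- (length(x) - 1) * 0.75 + 1
    xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
  }
  set.seed(123)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    x <- round(stats::rlnorm(n, 2, 1), 2)
    ref <- data.frame(persistence = x, motivation = x, compulsivity = x)
    expect_lt(abs(compute_thresholds(ref)[["persistence"]] - q75_brute(x)),
              1e-9)
  }

  # the parametric variant is mean + z(0.75) * SD
  refn <- data.frame(persistence = c(1, 2, 3, 4), motivation = c(1, 2, 3, 4),
                     compulsivity = c(1, 2, 3, 4))
  thn <- compute_thresholds(refn, method = "normal")
  expect_equal(unname(thn["persistence"]),
               2.5 + stats::qnorm(0.75) * stats::sd(c(1, 2, 3, 4)))

  expect_warning(compute_thresholds(ref[1:3, ]), "fewer than 4")
})

test_that("about a quarter of the reference group exceeds its own threshold", {
  # the ">= threshold" rule with a type-7 quantile flags at most
  # ceil(0.25 * n)-ish subjects: 25% plus at most one order statistic when
  # the interpolated quantile lands exactly on a sample value
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    x <- stats::rlnorm(n, 1, 0.6)  # continuous: no ties
    ref <- data.frame(persistence = x, motivation = x, compulsivity = x)
    th <- compute_thresholds(ref)
    frac <- mean(x >= th[["persistence"]])
    expect_lte(frac, 0.25 + 1 / n + 1e-12)
    expect_gte(frac, 0.25 - 1 / n - 1e-12)
  }
})

test_that("the 2-of-3 rule and threshold ties classify as printed", {
  th <- c(persistence = 10, motivation = 33, compulsivity = 5)
  sc <- data.frame(
    subject_id = c("low", "tie", "two_of_three"),
    persistence = c(1, 10, 12),
    motivation = c(5, 33, 51),
    compulsivity = c(0, 5, 2))
  cl <- classify_subjects(sc, th)
  expect_equal(cl$n_criteria, c(0L, 3L, 2L))
  expect_equal(cl$label, c("non_addicted", "addicted", "addicted"))
  expect_true(all(cl$label == ifelse(cl$n_criteria >= 2, "addicted",
                                     "non_addicted")))
})

test_that("classification is monotone in every single score", {
  set.seed(7)
  th <- c(persistence = 10, motivation = 33, compulsivity = 5)
  for (i in 1:200) {
    base <- data.frame(subject_id = "s",
                       persistence = stats::runif(1, 0, 20),
                       motivation = stats::runif(1, 0, 60),
                       compulsivity = stats::runif(1, 0, 10))
    before <- classify_subjects(base, th)
    bumped <- base
    cr <- sample(names(th), 1)
    bumped[[cr]] <- bumped[[cr]] + stats::runif(1, 0, 30)
    after <- classify_subjects(bumped, th)
    expect_gte(after$n_criteria, before$n_criteria)
    if (before$label == "addicted") expect_equal(after$label, "addicted")
  }
})

test_that("the extinction criterion needs 3 consecutive sessions under 35%", {
  base <- c(100, 100, 100)
  # 34 < 35 = 0.35 * 100: reached on the third session
  r1 <- check_extinction(base, rep(34, 6))
  expect_true(r1$reached)
  expect_equal(r1$session_reached, 3L)

  # boundary is strict: 35 is not < 35% of baseline
  expect_false(check_extinction(base, rep(35, 10))$reached)

  # an interruption restarts the run: first 3-run is sessions 3..5
  r3 <- check_extinction(base, c(34, 60, 34, 34, 34))
  expect_true(r3$reached)
  expect_equal(r3$session_reached, 5L)

  expect_error(check_extinction(c(0, 0, 0), rep(1, 5)), "baseline mean")
  expect_error(check_extinction(c(10, 10), rep(1, 5)), "3 values")
})

test_that("each criterion flags an extreme subpopulation of the reference group", {
  sweep <- recovery_sweep(n_seeds = 20L, n_subjects = 60L)
  pos <- t(vapply(sweep, `[[`, numeric(3), "ref_positive"))
  avg <- colMeans(pos)
  # seed-averaged per-criterion positive fraction in the reference group
  # sits in the extreme-subpopulation band around the 75th percentile
  for (cr in colnames(pos)) {
    expect_gte(avg[[cr]], 0.15)
    expect_lte(avg[[cr]], 0.35)
  }
})

test_that("scoring is replay-stable through CSV serialization", {
  set.seed(13)
  prof <- sample_cohort(cohort_spec(n_subjects = 1, seed = 13))[1, ]
  log <- run_fr_session(cfg, trait_agent(prof), fr_value = 2L,
                        session_index = 7L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log, f)
  expect_equal(summarize_session(read_event_log(f), cfg),
               summarize_session(log, cfg))
})
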