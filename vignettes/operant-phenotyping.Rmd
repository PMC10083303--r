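---
title: "Simulating and phenotyping operant cannabinoid self-administration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and phenotyping operant cannabinoid self-administration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operantSA)
```

## The model

`operantSA` implements, end to end, the computational skeleton of a mouse
model of cannabinoid (WIN 55,212-2) intravenous self-administration used to
phenotype addiction-like behavior. The package has three layers:

1. a **discrete-event session engine** that enforces the operant
   contingencies of each session type — fixed-ratio (FR1/FR2) training with
   a priming infusion, a mid-session drug-free period, post-infusion
   timeouts and a 50-reinforcer cap; a progressive-ratio (PR) session whose
   response requirement escalates along a fixed 35-value series; a foot-shock
   punishment test; extinction; and cue-induced reinstatement;
2. a **stochastic behavioral agent** whose latent traits (response rates,
   impulsivity, perseverance, a PR give-up threshold, shock tolerance,
   extinction decay) generate realistic per-mouse nose-poke streams, with
   ground-truth vulnerable/resilient labels for validating the pipeline; and
3. a **phenotyping and statistics layer** that turns event logs into the
   three addiction criteria — *persistence* (drug-free-period responding),
   *motivation* (PR breaking point) and *compulsivity* (shocks accepted) —
   plus two craving parameters (resistance to extinction, cue-induced
   drug seeking) and two phenotypic traits (impulsivity, reward
   sensitivity), thresholds them at the 75th percentile of a reference
   group, applies the 2-of-3 addicted/non-addicted rule, and runs the
   group-level statistics (normality-gated two-group tests, Mann-Whitney U,
   chi-square, Pearson correlation matrices, mixed-design repeated-measures
   ANOVA with Fisher LSD, and varimax-rotated PCA with the
   eigenvalue-greater-than-1 retention rule).

The protocol parameters default to the printed values of the study design:
125-min FR sessions (two 55-min active periods around a 15-min drug-free
period), a 10-s timeout, 50 reinforcers maximum, a 4-h PR cap with a 1-h
any-hole inactivity stop, a 50-min shock test with a 1-min pairing window,
ten 2-h extinction sessions, a 35% extinction criterion, and a 90-min
reinstatement session whose last 30 min restore the cues.

```{r}
default_protocol()
```

## A worked session

```{r}
cfg <- default_protocol()
log <- run_fr_session(cfg, periodic_agent(5), fr_value = 1L)
summarize_session(log, cfg)[, c("reinforcers", "duration_s", "end_reason")]
```

An agent poking every 5 s under FR1 earns one infusion per 10-s timeout
cycle and hits the 50-reinforcer cap at 495 s, long before the 125-min cap.

## Engine semantics and numerical choices

* **Time** is continuous seconds internally; events are committed at
  millisecond resolution and serialized with three decimals. A log written
  to CSV and read back reproduces the file byte for byte, and re-summarizing
  a parsed log gives exactly the in-memory summary.
* **Tie precedence** at equal timestamps is fixed for reproducibility:
  session-phase events (house light, drug-free boundaries, cue-phase start,
  and `timeout_end`) precede pokes, which precede shock, infusion, cue and
  `timeout_start` events, with `session_end` always last. `timeout_end` is
  grouped with the phase events because the timeout interval is half-open —
  a poke at exactly the end of a timeout is eligible, so the serialized
  order must show the timeout ending first or replays would disagree with
  the live engine.
* **Timeout and drug-free pokes** are logged but never reinforced and do
  not advance the FR/PR ratio counter; counting them would make the timeout
  meaningless.
* The **priming infusion** is non-contingent, logged as its own event type,
  and never counts toward the reinforcer cap or any score. It is emitted in
  FR-kind sessions only (training and the post-PR stabilizer): extinction
  explicitly withholds priming, and the PR/shock tests are probe sessions.
* The **cue light** is signaled on at the infusion instant and off again at
  the timeout start (the cue is dark during the timeout); the cue pulse and
  the timeout markers share the infusion's timestamp.
* The **PR inactivity rule** is a sliding window: the session ends at the
  first instant with no poke on either hole during the preceding hour.
  Exhausting the ratio series also ends the session.
* The **shock-session pairing window** is inclusive: a second response
  exactly 60 s after the first still completes the pair; a later response
  restarts the cycle as a new first step (and itself draws a shock).
* **Agents** are re-polled whenever a scheduled transition (phase change,
  timeout end) occurs before their proposed poke. For the stochastic agent
  this makes responding a piecewise-exponential renewal process — re-drawing
  an exponential wait at a hazard change is distributionally exact by
  memorylessness. Scripted agents keep absolute poke times, so re-polling
  never perturbs a deterministic schedule; identical agents and seeds give
  byte-identical logs.

## Phenotyping choices

* **Scoring windows.** Persistence and impulsivity average the three FR
  sessions immediately preceding the PR test; reward sensitivity averages
  the reinforcers of the last three FR2 sessions before the PR. The mean is
  used as the 3-day aggregator throughout. Averaged scores are reported to
  `1e-6` so serialized score tables classify identically to in-memory ones.
* **Thresholds.** The 75th percentile uses the empirical quantile with
  linear interpolation between order statistics (type 7). The protocol text
  speaks of a "normal distribution" of the reference group without a
  parametric recipe; a `method = "normal"` switch
  (mean + 0.674 SD) is provided. A subject is positive when its score is
  *equal to or beyond* the threshold, and subjects with 2 or 3 positive
  criteria are labeled addicted.
* **Reference group.** Thresholds default to the designated control group
  (first group level, e.g. "saline"); `threshold_scope = "within_group"`
  instead thresholds each group on its own distribution. The source
  protocol is ambiguous between the two readings, so both are first-class
  options and the default is documented rather than presented as the
  definitive intent.
* **Exclusions.** Subjects flagged as catheter-patency dropouts, or failing
  any acquisition condition (≤20% day-to-mean reinforcer deviation over the
  last three training days, ≥75% pooled active-hole responding, ≥5
  reinforcers every day), are excluded before thresholds are computed.
* **Extinction criterion.** Reached when active responding is strictly
  below 35% of the mean of the last three self-administration days for
  three consecutive extinction sessions; the baseline is taken from the
  last three FR-kind sessions before extinction (FR2 training and the
  stabilizer), the closest available analog of "the last 3 days of
  self-administration".
* **Drug seeking** is the active-poke count over the whole 90-min
  reinstatement session; the 30-min cue-phase count can be recovered from
  the event log.

## Statistical layer

Two-group comparisons are gated on a Lilliefors-corrected
Kolmogorov-Smirnov normality check (α = 0.05) of each sample: Student's
t-test (pooled variance) when both pass, otherwise the two-sided
Mann-Whitney U with U reported as min(U1, U2) — exact for group sizes up to
12 without ties, tie-corrected normal approximation otherwise. Zero-variance
samples route to Mann-Whitney with a warning. The chi-square test on 2×2
prevalence tables is Pearson's without continuity correction (a flag
enables Yates). Mixed-design RM-ANOVA is fitted with subjects as the error
stratum; effects with zero sum of squares are reported as F = 0, p = 1, and
Fisher LSD tables are unadjusted pairwise t-tests on the matching ANOVA
error term. PCA standardizes the seven behavioral variables, retains
components with eigenvalue > 1, and varimax-rotates the retained loadings
(normalized Kaiser, tolerance 1e-8, up to 1000 iterations); explained
variance is reported from the unrotated eigenvalues, with post-rotation
sums of squared loadings alongside, because the study's variance figures do
not state which convention they use. Loadings are sign-fixed so each
component's largest-magnitude loading is positive. No multiple-testing
correction is applied anywhere, matching the source analyses (which use
none).

## What the synthetic cohort emulates — and what it does not

The generator's defaults describe a 60-subject cohort, 30% of it drawn from
a "vulnerable" trait population, randomized 50/50 to two treatment groups,
with a 1-in-30 catheter-failure dropout rate. Traits are log-normal (rates,
multipliers), Beta (shock tolerance) or drawn from ratio-series values (the
PR give-up threshold):

* vulnerable agents carry higher perseverance (drug-free responding),
  higher impulsivity, higher give-up ratios ({51, 75, 90} vs
  {5, 12, 21, 33}), higher shock tolerance and slower extinction decay, so
  the three criteria separate the planted subpopulations the way the
  addicted extreme separates in real cohorts;
* FR2 poke rates are set so that free-running reinforcer counts sit near
  the 50-reinforcer cap. This is a deliberate compromise: a memoryless
  (exponential) poke process at the ~20 reinforcers-per-session level of
  real mice has day-to-day Poisson variability far above the 20% stability
  criterion, which would exclude most of the cohort; letting the cap
  truncate the counts keeps acquisition rates realistic at the cost of
  compressed reward-sensitivity variance. Real mice pace their responding
  (negatively autocorrelated inter-poke intervals), which no renewal
  process reproduces;
* the vulnerable rate distribution is bounded so that the 50th reinforcer
  cannot arrive before the drug-free period begins (eligible rate ×
  2 pokes + 10-s timeout per infusion must exceed 55 min for 50 infusions).
  Without this bound the engine ends the fastest sessions before the
  drug-free period, recording persistence = 0 for exactly the most
  vulnerable subjects — a protocol artifact impossible in the real design,
  where counts stay far from the cap.

Passing the recovery tests therefore shows that the pipeline's scoring,
thresholding and classification are faithful to the stated rules and can
recover a planted two-population structure at realistic sample sizes; it
does not show that real mice follow exponential renewal dynamics, nor
calibrate any trait distribution to real data (none are deposited).

## Problem sizes used by the test suite

The planted-phenotype recovery check simulates 20 cohorts of 60 agents
(30% vulnerable) through the criteria stages (5 FR1, 5 FR2, PR, FR2
stabilizer, shock — the sessions that feed the 2-of-3 classification) and
requires seed-averaged sensitivity and specificity of at least 0.8 against
the ground-truth labels. The full 24-session protocol, including the ten
extinction sessions and reinstatement, is exercised on smaller cohorts.
Oracle-equivalence suites compare Mann-Whitney U with exhaustive pair
counting at group sizes up to 12, chi-square with the direct
sum((O−E)²/E), percentile thresholds with a sort-based computation, and
varimax rotations with the communality-preservation identity at 1e-9.

## Known limitations

* No pharmacokinetics: dose fields are metadata; infusions have no
  behavioral feedback beyond the schedule contingencies.
* The agent is memoryless within a phase; bursting, satiation within a
  session, and win-stay/lose-shift structure are not modeled.
* The shock test's "different operant box" context is not modeled and has
  no behavioral consequence.
* Trait defaults are nominal: the source study deposits no per-animal data
  that could calibrate them.
* Only the abstract 2-of-3 classification is implemented; no continuous
  addiction-severity index beyond the 0–3 criteria count.
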