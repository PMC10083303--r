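## Synthetic-cohort specification and sampling.

TRAIT_NAMES <- c("base_active_rate", "base_inactive_rate", "learning_gain",
                 "impulsivity", "perseverance", "motivation",
                 "shock_tolerance", "extinction_decay", "burst_gain",
                 "cue_gain")

#' Default per-phenotype trait distributions
#'
#' Nominal distributions for the latent traits of resilient and vulnerable
#' agents. Rates and multipliers are log-normal; the PR give-up threshold
#' (`motivation`) is drawn from low vs high values of the PR ratio series;
#' shock tolerance is Beta-distributed. The two phenotypes separate on
#' perseverance (drug-free responding), give-up ratio and shock tolerance,
#' mirroring the construct that compulsive, highly motivated, persistent
#' responders form the vulnerable extreme of the population. Values were
#' chosen so that free-running FR2 reinforcer counts sit near the
#' 50-reinforcer cap (making the acquisition stability criterion attainable
#' for a memoryless poke process) and so that give-up ratios are reachable
#' within the 4-h PR cap at the implied poke rates; see the methods
#' vignette for the full rationale.
#'
#' Each trait is specified as `list(dist, ...)` with `dist` one of
#' `"lnorm"` (`meanlog`, `sdlog`), `"beta"` (`shape1`, `shape2`),
#' `"choice"` (`values`, optional `probs`) or `"fixed"` (`value`).
#'
#' @return Named list with elements `resilient` and `vulnerable`, each a
#'   named list of trait distribution specs.
#' @export
default_trait_distributions <- function() {
  list(
    resilient = list(
      base_active_rate   = list(dist = "lnorm", meanlog = log(0.65), sdlog = 0.22),
      base_inactive_rate = list(dist = "lnorm", meanlog = log(0.12), sdlog = 0.40),
      learning_gain      = list(dist = "lnorm", meanlog = log(1.8), sdlog = 0.12),
      impulsivity        = list(dist = "lnorm", meanlog = log(0.8), sdlog = 0.40),
      perseverance       = list(dist = "lnorm", meanlog = log(0.6), sdlog = 0.40),
      motivation         = list(dist = "choice", values = c(5, 12, 21, 33)),
      shock_tolerance    = list(dist = "beta", shape1 = 5, shape2 = 5),
      extinction_decay   = list(dist = "lnorm", meanlog = log(0.45), sdlog = 0.30),
      burst_gain         = list(dist = "lnorm", meanlog = log(0.3), sdlog = 0.40, shift = 1),
      cue_gain           = list(dist = "lnorm", meanlog = log(0.5), sdlog = 0.40, shift = 1)
    ),
    vulnerable = list(
      ## rate bounded so the FR2 reinforcer cap is not reached inside the
      ## first 55-min active period (eligible rate x learning < 2.1/min),
      ## which would end the session before the drug-free period and zero
      ## the persistence measurement
      base_active_rate   = list(dist = "lnorm", meanlog = log(0.70), sdlog = 0.15),
      base_inactive_rate = list(dist = "lnorm", meanlog = log(0.12), sdlog = 0.40),
      learning_gain      = list(dist = "lnorm", meanlog = log(2.2), sdlog = 0.10),
      impulsivity        = list(dist = "lnorm", meanlog = log(2.5), sdlog = 0.35),
      perseverance       = list(dist = "lnorm", meanlog = log(3.0), sdlog = 0.35),
      motivation         = list(dist = "choice", values = c(51, 75, 90)),
      shock_tolerance    = list(dist = "beta", shape1 = 12, shape2 = 2),
      extinction_decay   = list(dist = "lnorm", meanlog = log(0.12), sdlog = 0.30),
      burst_gain         = list(dist = "lnorm", meanlog = log(1.5), sdlog = 0.30, shift = 1),
      cue_gain           = list(dist = "lnorm", meanlog = log(2.0), sdlog = 0.30, shift = 1)
    )
  )
}

sample_trait <- function(spec, n) {
  if (is.null(spec$dist)) stop("config error: trait spec without 'dist'",
                               call. = FALSE)
  out <- switch(spec$dist,
    lnorm = {
      if (!is.finite(spec$meanlog) || !is.finite(spec$sdlog) || spec$sdlog < 0)
        stop("config error: invalid lnorm parameters", call. = FALSE)
      shift <- if (is.null(spec$shift)) 0 else spec$shift
      shift + stats::rlnorm(n, spec$meanlog, spec$sdlog)
    },
    beta = {
      if (spec$shape1 <= 0 || spec$shape2 <= 0)
        stop("config error: invalid beta parameters", call. = FALSE)
      stats::rbeta(n, spec$shape1, spec$shape2)
    },
    choice = {
      if (!length(spec$values))
        stop("config error: choice with no values", call. = FALSE)
      spec$values[sample.int(length(spec$values), n, replace = TRUE,
                             prob = spec$probs)]
    },
    fixed = rep(spec$value, n),
    stop("config error: unknown trait distribution '", spec$dist, "'",
         call. = FALSE)
  )
  out
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Number of subjects.
#' @param fraction_vulnerable Probability each subject is of the vulnerable
#'   (ground-truth addicted-prone) phenotype.
#' @param trait_distributions Per-phenotype trait distributions, as from
#'   [default_trait_distributions()].
#' @param group_levels,group_probs Treatment-group labels and assignment
#'   probabilities (independent of phenotype). The first level is the
#'   designated reference (control) group for thresholding.
#' @param dropout_prob Probability a subject is flagged as a
#'   catheter-patency dropout and excluded from phenotyping.
#' @param seed Integer seed; the spec plus seed fully determines the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 60L,
                        fraction_vulnerable = 0.3,
                        trait_distributions = default_trait_distributions(),
                        group_levels = c("saline", "cno"),
                        group_probs = c(0.5, 0.5),
                        dropout_prob = 1 / 30,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, fraction_vulnerable >= 0,
            fraction_vulnerable <= 1,
            length(group_levels) == length(group_probs),
            all(group_probs >= 0), sum(group_probs) > 0,
            dropout_prob >= 0, dropout_prob < 1)
  for (lab in c("resilient", "vulnerable")) {
    d <- trait_distributions[[lab]]
    if (is.null(d) || !all(TRAIT_NAMES %in% names(d))) {
      stop("config error: trait_distributions$", lab,
           " must specify all of: ", paste(TRAIT_NAMES, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 fraction_vulnerable = fraction_vulnerable,
                 trait_distributions = trait_distributions,
                 group_levels = group_levels,
                 group_probs = group_probs / sum(group_probs),
                 dropout_prob = dropout_prob,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a cohort of trait profiles
#'
#' Draws `n_subjects` latent trait profiles with ground-truth
#' vulnerable/resilient labels, treatment-group assignment and a
#' catheter-patency dropout flag. Fully reproducible from the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Overrides `spec$seed` when not `NULL`.
#' @return A data.frame of class `cohort` with one row per subject:
#'   `subject_id`, `ground_truth_label`, `group`, `dropout`, and one column
#'   per trait.
#' @export
sample_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(if (is.null(seed)) spec$seed else seed)
  n <- spec$n_subjects
  label <- ifelse(stats::runif(n) < spec$fraction_vulnerable,
                  "vulnerable", "resilient")
  group <- spec$group_levels[
    sample.int(length(spec$group_levels), n, replace = TRUE,
               prob = spec$group_probs)]
  dropout <- stats::runif(n) < spec$dropout_prob
  traits <- matrix(NA_real_, n, length(TRAIT_NAMES),
                   dimnames = list(NULL, TRAIT_NAMES))
  for (lab in c("resilient", "vulnerable")) {
    idx <- which(label == lab)
    if (!length(idx)) next
    for (tr in TRAIT_NAMES) {
      traits[idx, tr] <- sample_trait(spec$trait_distributions[[lab]][[tr]],
                                      length(idx))
    }
  }
  out <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                    ground_truth_label = label,
                    group = group,
                    dropout = dropout,
                    traits,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Read / write a cohort specification as YAML
#'
#' The YAML mirrors the [cohort_spec()] fields, with
#' `trait_distributions` as a nested `resilient`/`vulnerable` mapping of
#' trait distribution specs. A defaults file ships in
#' `system.file("extdata", "cohort_default.yaml", package = "operantSA")`.
#'
#' @param path File path.
#' @return `read_cohort_spec()` returns a validated `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_spec))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("config error: unknown cohort spec keys: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(cohort_spec, vals)
}

#' @rdname read_cohort_spec
#' @param spec A `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  yaml::write_yaml(unclass(spec), path, precision = 15L)
  invisible(path)
}

#' Write / read cohort ground truth as CSV
#'
#' Exports `subject_id,ground_truth_label,group,dropout,<trait columns>`
#' for downstream recovery scoring.
#'
#' @param cohort A `cohort` data.frame.
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}
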