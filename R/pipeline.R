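## End-to-end orchestration: simulate a cohort through the full protocol,
## phenotype the event logs, and run the group-level analyses.

#' Session plan for the full protocol
#'
#' The complete experimental sequence: FR1 training, FR2 training, the PR
#' test, a stabilizing FR2 session, the shock test, extinction, and the
#' cue-induced reinstatement session. `session_index` carries the
#' training-session counter (FR sessions continue counting through the
#' stabilizer) or the extinction-session counter; the reinstatement session
#' continues the extinction counter so agent response decay carries over.
#'
#' @param config A [protocol_config()].
#' @param stages Subset of protocol stages to include, in protocol order.
#' @return data.frame: `stage`, `session_id`, `kind`, `fr_value`,
#'   `session_index`.
#' @export
protocol_sessions <- function(config = default_protocol(),
                              stages = c("fr1", "fr2", "pr", "stabilizer",
                                         "shock", "extinction",
                                         "reinstatement")) {
  stages <- match.arg(stages, several.ok = TRUE,
                      choices = c("fr1", "fr2", "pr", "stabilizer", "shock",
                                  "extinction", "reinstatement"))
  rows <- list()
  push <- function(stage, id, kind, fr, idx) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, session_id = id, kind = kind, fr_value = fr,
      session_index = idx, stringsAsFactors = FALSE)
  }
  n1 <- config$n_fr1_sessions; n2 <- config$n_fr2_sessions
  if ("fr1" %in% stages) {
    for (i in seq_len(n1)) push("fr1", sprintf("FR1_%02d", i), "FR", 1L, i)
  }
  if ("fr2" %in% stages) {
    for (i in seq_len(n2)) push("fr2", sprintf("FR2_%02d", i), "FR", 2L, n1 + i)
  }
  if ("pr" %in% stages) push("pr", "PR_01", "PR", NA_integer_, 1L)
  if ("stabilizer" %in% stages) {
    push("stabilizer", sprintf("FR2_%02d", n2 + 1L), "FR", 2L, n1 + n2 + 1L)
  }
  if ("shock" %in% stages) push("shock", "SHOCK_01", "SHOCK", NA_integer_, 1L)
  if ("extinction" %in% stages) {
    for (i in seq_len(config$n_extinction_sessions)) {
      push("extinction", sprintf("EXT_%02d", i), "EXTINCTION", NA_integer_, i)
    }
  }
  if ("reinstatement" %in% stages) {
    push("reinstatement", "REINST_01", "REINSTATEMENT", NA_integer_,
         config$n_extinction_sessions + 1L)
  }
  do.call(rbind, rows)
}

#' Simulate a cohort through the self-administration protocol
#'
#' Samples a cohort of latent-trait agents and runs each subject through
#' the protocol sequence, producing one event log per subject-session.
#' Fully deterministic given `seed`. When `out_dir` is given, one CSV per
#' log, the cohort ground-truth CSV and a run manifest (seed, package
#' version, per-file MD5 checksums) are written there.
#'
#' @param spec A [cohort_spec()].
#' @param config A [protocol_config()].
#' @param seed Integer seed for the whole run (cohort + sessions);
#'   defaults to `spec$seed`.
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @param stages Protocol stages to run (see [protocol_sessions()]).
#' @return Invisibly, a list: `cohort`, `logs` (list of [event_log()]s
#'   named `subject/session`), `plan`, `manifest` (or `NULL`).
#' @export
simulate_experiment <- function(spec = cohort_spec(),
                                config = default_protocol(),
                                seed = spec$seed,
                                out_dir = NULL,
                                stages = c("fr1", "fr2", "pr", "stabilizer",
                                           "shock", "extinction",
                                           "reinstatement")) {
  cohort <- sample_cohort(spec, seed = seed)
  plan <- protocol_sessions(config, stages)
  logs <- vector("list", nrow(cohort) * nrow(plan))
  nm <- character(length(logs))
  k <- 0L
  for (si in seq_len(nrow(cohort))) {
    profile <- cohort[si, ]
    for (pi in seq_len(nrow(plan))) {
      agent <- trait_agent(profile)   # fresh agent per session
      row <- plan[pi, ]
      log <- run_session_impl(row$kind, config, agent,
                              subject_id = profile$subject_id,
                              session_id = row$session_id,
                              session_index = row$session_index,
                              fr_value = if (is.na(row$fr_value)) {
                                config$fr_value
                              } else row$fr_value)
      k <- k + 1L
      logs[[k]] <- log
      nm[k] <- paste0(profile$subject_id, "/", row$session_id)
    }
  }
  names(logs) <- nm
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ## file names carry the protocol position so that sorted file order is
    ## chronological order (phenotyping depends on it)
    files <- character(0)
    for (i in seq_along(logs)) {
      log <- logs[[i]]
      pos <- (i - 1L) %% nrow(plan) + 1L
      f <- file.path(out_dir, sprintf("%s_%02d_%s.csv", log$subject_id,
                                      pos, log$session_id))
      write_event_log(log, f)
      files <- c(files, f)
    }
    cf <- file.path(out_dir, "cohort_ground_truth.csv")
    write_cohort_csv(cohort, cf)
    files <- c(files, cf)
    manifest <- list(
      seed = seed,
      package_version = as.character(utils::packageVersion("operantSA")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      n_subjects = nrow(cohort),
      n_sessions = nrow(plan),
      files = data.frame(path = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(cohort = cohort, logs = logs, plan = plan,
                 manifest = manifest))
}

#' Read all event logs from a directory
#'
#' Logs are returned in sorted file-name order, which must correspond to
#' chronological order per subject ([simulate_experiment()] encodes the
#' protocol position in the file name; name user-supplied logs
#' accordingly).
#'
#' @param dir Directory of per-session event-log CSVs.
#' @return Named list of [event_log()]s.
#' @export
read_event_log_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "cohort_ground_truth.csv"]
  logs <- lapply(files, read_event_log)
  names(logs) <- vapply(logs, function(l) {
    paste0(l$subject_id, "/", l$session_id)
  }, character(1L))
  logs
}

#' Phenotype a cohort of event logs
#'
#' Runs the full scoring and classification pipeline: per-session
#' summaries, exclusion of catheter-patency dropouts and of subjects
#' failing the acquisition criteria (checked on the three FR sessions
#' before the PR test), criterion scores, 75th-percentile thresholds from
#' the reference group, the 2-of-3 classification, and the extinction
#' criterion (baseline = active pokes of the last three FR sessions before
#' extinction).
#'
#' @param logs Named list of [event_log()]s in chronological order per
#'   subject (as from [simulate_experiment()] or [read_event_log_dir()]).
#' @param config A [protocol_config()].
#' @param cohort Optional cohort table supplying `group` and `dropout`
#'   per subject.
#' @param reference_group Group whose score distribution sets the
#'   thresholds (default: first group level, the designated control);
#'   ignored when `threshold_scope = "within_group"`.
#' @param threshold_scope `"reference"` (one set of thresholds from the
#'   reference group, applied to everyone) or `"within_group"` (each group
#'   thresholded on its own distribution).
#' @param percentile_method Passed to [compute_thresholds()].
#' @return A list of class `phenotyping_result`: `scores` (one row per
#'   included subject, with flags, `n_criteria`, `label`, extinction
#'   fields), `thresholds`, `exclusions` (subject, reason), `summaries`.
#' @export
phenotype_cohort <- function(logs, config = default_protocol(),
                             cohort = NULL,
                             reference_group = NULL,
                             threshold_scope = c("reference", "within_group"),
                             percentile_method = c("empirical", "normal")) {
  threshold_scope <- match.arg(threshold_scope)
  percentile_method <- match.arg(percentile_method)
  summaries <- summarize_sessions(logs, config)
  subjects <- unique(summaries$subject_id)
  group_of <- function(sid) {
    if (!is.null(cohort) && "group" %in% names(cohort)) {
      g <- cohort$group[cohort$subject_id == sid]
      if (length(g)) g[1L] else "all"
    } else "all"
  }
  exclusions <- data.frame(subject_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  exclude <- function(sid, why) {
    exclusions <<- rbind(exclusions,
                         data.frame(subject_id = sid, reason = why,
                                    stringsAsFactors = FALSE))
  }
  score_rows <- list()
  for (sid in subjects) {
    ss <- summaries[summaries$subject_id == sid, , drop = FALSE]
    if (!is.null(cohort) && "dropout" %in% names(cohort)) {
      dr <- cohort$dropout[cohort$subject_id == sid]
      if (length(dr) && isTRUE(as.logical(dr[1L]))) {
        exclude(sid, "catheter patency dropout")
        next
      }
    }
    sc <- tryCatch(compute_scores(ss), error = function(e) conditionMessage(e))
    if (is.character(sc)) { exclude(sid, sc); next }
    pr_i <- which(ss$session_kind == "PR")[1L]
    pre_fr <- which(ss$session_kind == "FR" & seq_len(nrow(ss)) < pr_i)
    acq <- check_acquisition(ss[utils::tail(pre_fr, 3L), , drop = FALSE])
    if (!acq$passed) {
      exclude(sid, sprintf(
        "failed acquisition (stability %s, discrimination %s, reinforcers %s)",
        acq$stability_ok, acq$discrimination_ok, acq$reinforcers_ok))
      next
    }
    sc$group <- group_of(sid)
    ## extinction criterion
    ext_i <- which(ss$session_kind == "EXTINCTION")
    if (length(ext_i) >= 3L) {
      pre_ext_fr <- which(ss$session_kind == "FR" & seq_len(nrow(ss)) < ext_i[1L])
      base3 <- ss$active_pokes[utils::tail(pre_ext_fr, 3L)]
      chk <- check_extinction(base3, ss$active_pokes[ext_i])
      sc$extinction_reached <- chk$reached
      sc$extinction_session <- chk$session_reached
    } else {
      sc$extinction_reached <- NA
      sc$extinction_session <- NA_integer_
    }
    score_rows[[length(score_rows) + 1L]] <- sc
  }
  if (!length(score_rows)) {
    stop("no subjects left after exclusions", call. = FALSE)
  }
  scores <- do.call(rbind, score_rows)

  if (threshold_scope == "reference") {
    ref <- if (is.null(reference_group)) scores else {
      scores[scores$group == reference_group, , drop = FALSE]
    }
    if (!nrow(ref)) {
      stop("reference group '", reference_group, "' has no included subjects",
           call. = FALSE)
    }
    thresholds <- compute_thresholds(ref, method = percentile_method)
    scores <- classify_subjects(scores, thresholds)
  } else {
    parts <- split(scores, scores$group)
    thresholds <- lapply(parts, compute_thresholds, method = percentile_method)
    scores <- do.call(rbind, Map(classify_subjects, parts, thresholds))
    rownames(scores) <- NULL
  }
  structure(list(scores = scores, thresholds = thresholds,
                 exclusions = exclusions, summaries = summaries),
            class = "phenotyping_result")
}

#' @export
print.phenotyping_result <- function(x, ...) {
  cat(sprintf("<phenotyping_result> %d subjects included, %d excluded\n",
              nrow(x$scores), nrow(x$exclusions)))
  cat(sprintf("  addicted: %d (%.1f%%)\n", sum(x$scores$label == "addicted"),
              100 * mean(x$scores$label == "addicted")))
  if (is.numeric(x$thresholds)) {
    cat("  thresholds:",
        paste(sprintf("%s=%.3g", names(x$thresholds), x$thresholds),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Group-level statistical analysis of a scores table
#'
#' Runs the analysis surfaces of the phenotyping study on a per-subject
#' scores table: two-group comparisons for every score (normality-gated),
#' addicted vs non-addicted comparisons, a chi-square test on addiction
#' prevalence by group, correlations of each criterion with the number of
#' criteria met, per-label correlation matrices of the seven behavioral
#' variables, and the varimax-rotated PCA.
#'
#' @param scores data.frame from [phenotype_cohort()]`$scores` (or read
#'   back via [read_scores_csv()]).
#' @param group_col Grouping column (two levels used for group tests; with
#'   fewer than 2 groups the group comparisons are skipped with a warning).
#' @return A list of class `stats_report`.
#' @export
analyze_scores <- function(scores, group_col = "group") {
  stopifnot(is.data.frame(scores))
  vars <- intersect(SCORE_VARS, names(scores))
  groups <- if (group_col %in% names(scores)) {
    unique(scores[[group_col]])
  } else character(0)
  group_tests <- NULL
  chi_square <- NULL
  if (length(groups) >= 2L) {
    g1 <- scores[scores[[group_col]] == groups[1L], , drop = FALSE]
    g2 <- scores[scores[[group_col]] == groups[2L], , drop = FALSE]
    group_tests <- lapply(stats::setNames(vars, vars), function(v) {
      x <- g1[[v]][!is.na(g1[[v]])]; y <- g2[[v]][!is.na(g2[[v]])]
      if (length(x) >= 3L && length(y) >= 3L) compare_groups(x, y) else NULL
    })
    if ("label" %in% names(scores)) {
      tab <- table(factor(scores[[group_col]], levels = groups[1:2]),
                   factor(scores$label, levels = c("addicted", "non_addicted")))
      chi_square <- tryCatch(chi_square_2x2(tab),
                             error = function(e) conditionMessage(e))
    }
  } else {
    warning("fewer than 2 groups: group comparisons skipped")
  }
  label_tests <- NULL
  if ("label" %in% names(scores) &&
      length(unique(scores$label)) == 2L) {
    a <- scores[scores$label == "addicted", , drop = FALSE]
    na_ <- scores[scores$label == "non_addicted", , drop = FALSE]
    label_tests <- lapply(stats::setNames(vars, vars), function(v) {
      x <- a[[v]][!is.na(a[[v]])]; y <- na_[[v]][!is.na(na_[[v]])]
      if (length(x) >= 3L && length(y) >= 3L) compare_groups(x, y) else NULL
    })
  }
  criteria_cor <- NULL
  if ("n_criteria" %in% names(scores)) {
    criteria_cor <- lapply(stats::setNames(CRITERIA, CRITERIA), function(cr) {
      ok <- stats::complete.cases(scores[[cr]], scores$n_criteria)
      if (sum(ok) < 3L || stats::sd(scores[[cr]][ok]) == 0 ||
          stats::sd(scores$n_criteria[ok]) == 0) return(NULL)
      ct <- stats::cor.test(scores[[cr]][ok], scores$n_criteria[ok])
      list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    })
  }
  cor_by_label <- NULL
  if ("label" %in% names(scores)) {
    cor_by_label <- lapply(split(scores, scores$label), function(d) {
      pearson_correlation_matrix(d[vars])
    })
  }
  cc <- scores[stats::complete.cases(scores[vars]), vars, drop = FALSE]
  pca <- if (nrow(cc) >= length(vars) + 2L) {
    tryCatch(pca_varimax(cc), error = function(e) conditionMessage(e))
  } else NULL
  structure(list(variables = vars,
                 groups = groups,
                 group_tests = group_tests,
                 label_tests = label_tests,
                 chi_square = chi_square,
                 criteria_vs_n_criteria = criteria_cor,
                 correlations_by_label = cor_by_label,
                 correlations_all = pearson_correlation_matrix(scores[vars]),
                 pca = pca,
                 n_subjects = nrow(scores)),
            class = "stats_report")
}

#' Write a stats report to disk
#'
#' Serializes the test results as JSON and the correlation / loading
#' matrices as CSV files.
#'
#' @param report A `stats_report` from [analyze_scores()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_stats_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strip <- function(x) {
    if (inherits(x, "group_comparison")) {
      unclass(x)
    } else if (inherits(x, "correlation_matrix")) {
      NULL
    } else if (inherits(x, "pca_result")) {
      list(eigenvalues = x$eigenvalues,
           explained_variance_pct = x$explained_variance_pct,
           retained_components = x$retained_components,
           rotated_ss_pct = x$rotated_ss_pct)
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, strip)
    } else x
  }
  paths <- character(0)
  jf <- file.path(dir, "stats_report.json")
  jsonlite::write_json(strip(unclass(report)), jf, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  paths <- c(paths, jf)
  save_cor <- function(cm, stem) {
    if (is.null(cm) || !inherits(cm, "correlation_matrix")) return()
    for (what in c("r", "p")) {
      f <- file.path(dir, sprintf("%s_%s.csv", stem, what))
      utils::write.csv(cm[[what]], f)
      paths <<- c(paths, f)
    }
  }
  save_cor(report$correlations_all, "correlations_all")
  for (lab in names(report$correlations_by_label)) {
    save_cor(report$correlations_by_label[[lab]],
             paste0("correlations_", lab))
  }
  if (inherits(report$pca, "pca_result")) {
    f <- file.path(dir, "pca_loadings.csv")
    utils::write.csv(report$pca$loadings, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Figures: correlation heatmap and PCA loading chart
#'
#' Optional ggplot2 figures mirroring the study's analysis surfaces: a
#' correlation heatmap of the seven behavioral variables and a bar chart
#' of rotated loadings per retained component (dashed line at the 0.7
#' "strong loading" convention).
#'
#' @param cm A `correlation_matrix`.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(cm) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  stopifnot(inherits(cm, "correlation_matrix"))
  d <- expand.grid(x = cm$variables, y = cm$variables,
                   stringsAsFactors = FALSE)
  d$r <- as.vector(cm$r)
  d$x <- factor(d$x, levels = cm$variables)
  d$y <- factor(d$y, levels = rev(cm$variables))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1),
                                  name = "r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname plot_correlation_heatmap
#' @param pca A `pca_result`.
#' @export
plot_pca_loadings <- function(pca) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  stopifnot(inherits(pca, "pca_result"))
  L <- pca$loadings
  d <- data.frame(variable = rep(rownames(L), ncol(L)),
                  component = rep(colnames(L), each = nrow(L)),
                  loading = as.vector(L), stringsAsFactors = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$variable,
                                                     -abs(.data$loading)),
                                  y = .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-0.7, 0.7), linetype = "dashed") +
    ggplot2::facet_wrap(~ component) +
    ggplot2::labs(x = NULL, y = "rotated loading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
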