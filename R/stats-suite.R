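## Group statistics: normality-gated two-group tests, chi-square,
## correlation matrices, mixed-design repeated-measures ANOVA with Fisher
## LSD, and varimax-rotated PCA.

ks_normality_p <- function(x) {
  ## Lilliefors-corrected one-sample KS test against a normal with
  ## estimated mean and SD; undefined for n < 5 or zero variance.
  if (length(x) < 5L || stats::sd(x) == 0) return(NA_real_)
  nortest::lillie.test(x)$p.value
}

#' Mann-Whitney U statistic and two-sided test
#'
#' U1 is computed from the rank sum of `x`; U is reported as the smaller of
#' U1 and U2 (the SPSS convention). The p-value is exact for
#' n1, n2 <= `exact_max` without ties, and uses the tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for which the exact null
#'   distribution is used (default 12).
#' @return List: `U`, `U1`, `U2`, `p_value`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- n1 <= exact_max && n2 <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = min(u1, u2), U1 = u1, U2 = u2, p_value = wt$p.value)
}

#' Two-group comparison with a normality gate
#'
#' Compares two samples with Student's t-test when both pass a
#' Kolmogorov-Smirnov (Lilliefors) normality check at `alpha_normality`,
#' and with the two-sided Mann-Whitney U test otherwise. Degenerate samples
#' (zero variance, or too few values for the normality test) are routed to
#' Mann-Whitney with a warning. U is reported as the smaller of U1 and U2;
#' its p-value is exact for n1, n2 <= 12 without ties and uses the
#' tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param alpha_normality Normality-gate level (default 0.05).
#' @return A list of class `group_comparison`: `test_name`
#'   (`"student_t"` or `"mann_whitney_u"`), `statistic`, `p_value`, `n1`,
#'   `n2`, `normality_p_values`.
#' @export
compare_groups <- function(x, y, alpha_normality = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3L || n2 < 3L) stop("each group needs n >= 3", call. = FALSE)
  px <- ks_normality_p(x); py <- ks_normality_p(y)
  normal <- !is.na(px) && !is.na(py) && px >= alpha_normality &&
    py >= alpha_normality
  if (is.na(px) || is.na(py)) {
    warning("degenerate sample(s): normality test undefined, using Mann-Whitney U")
  }
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    res <- list(test_name = "student_t",
                statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    mw <- mann_whitney_u(x, y)
    res <- list(test_name = "mann_whitney_u",
                statistic = mw$U,
                p_value = mw$p_value)
  }
  res$n1 <- n1; res$n2 <- n2
  res$normality_p_values <- c(x = px, y = py)
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (`correct = TRUE` applies
#' Yates' correction), df = 1.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param correct Apply Yates' continuity correction.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2", call. = FALSE)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: chi-square undefined", call. = FALSE)
  }
  ct <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations with two-sided p-values per pair.
#' Pairs with fewer than 3 complete observations or a zero-variance member
#' are reported as `NA`.
#'
#' @param data Numeric data.frame or matrix (subjects x variables).
#' @param variables Columns to include, in display order (defaults to all).
#' @return A list of class `correlation_matrix`: `variables`, symmetric
#'   matrices `r` and `p`, and `n` complete observations per pair.
#' @export
pearson_correlation_matrix <- function(data, variables = colnames(data)) {
  data <- as.data.frame(data)[variables]
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  n <- matrix(0L, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in i:k) {
      xi <- data[[i]]; xj <- data[[j]]
      ok <- stats::complete.cases(xi, xj)
      n[i, j] <- n[j, i] <- sum(ok)
      if (i == j) {
        if (sum(ok) >= 1L && stats::sd(xi[ok]) > 0) {
          r[i, j] <- 1; p[i, j] <- 0
        }
        next
      }
      if (sum(ok) < 3L || stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
      ct <- stats::cor.test(xi[ok], xj[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(variables = variables, r = r, p = p, n = n),
            class = "correlation_matrix")
}

#' Mixed-design repeated-measures ANOVA with Fisher LSD post hoc tests
#'
#' Two-way mixed ANOVA with a between-subject factor (group) and a
#' within-subject factor (session), fitted via `stats::aov` with subjects
#' as the error stratum. Requires a complete balanced design (every subject
#' observed once per session; no imputation). Effects with zero sum of
#' squares are reported as F = 0, p = 1. Fisher LSD tables are unadjusted
#' pairwise t-tests using the corresponding ANOVA error term: group pairs
#' use the between-subject mean square, session pairs the within-subject
#' residual mean square.
#'
#' @param data Long-format data.frame.
#' @param subject,group,session,value Column names.
#' @return A list of class `rm_anova`: `anova_table` (effect, df1, df2, F,
#'   p), `post_hoc` (pairwise LSD table), and the fitted `aov` object.
#' @export
rm_anova <- function(data, subject = "subject", group = "group",
                     session = "session", value = "value") {
  d <- data.frame(subject = factor(data[[subject]]),
                  group = factor(data[[group]]),
                  session = factor(data[[session]]),
                  value = as.numeric(data[[value]]))
  if (anyNA(d$value)) stop("missing cells: no imputation", call. = FALSE)
  tab <- table(d$subject, d$session)
  if (any(tab != 1L)) {
    stop("missing cells: every subject must be observed exactly once per session",
         call. = FALSE)
  }
  gps <- table(unique(d[c("subject", "group")])$group)
  if (any(gps < 2L)) stop("need >= 2 subjects per group", call. = FALSE)

  fit <- stats::aov(value ~ group * session + Error(subject), data = d)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1L]])
  within <- as.data.frame(s[["Error: Within"]][[1L]])
  get_row <- function(df, nm) df[trimws(rownames(df)) == nm, , drop = FALSE]
  eff <- function(df, nm, err) {
    row <- get_row(df, nm)
    ssq <- row[["Sum Sq"]]
    msq <- row[["Mean Sq"]]
    mse <- err[["Mean Sq"]]
    f <- if (ssq < 1e-12) 0 else if (mse <= 0) NA_real_ else msq / mse
    p <- if (ssq < 1e-12) 1 else if (is.na(f)) NA_real_ else {
      stats::pf(f, row[["Df"]], err[["Df"]], lower.tail = FALSE)
    }
    data.frame(effect = nm, df1 = row[["Df"]], df2 = err[["Df"]],
               F = f, p = p, stringsAsFactors = FALSE)
  }
  err_b <- get_row(between, "Residuals")
  err_w <- get_row(within, "Residuals")
  anova_table <- rbind(eff(between, "group", err_b),
                       eff(within, "session", err_w),
                       eff(within, "group:session", err_w))

  ## Fisher LSD
  n_sess <- nlevels(d$session)
  subj_group <- unique(d[c("subject", "group")])
  n_per_group <- table(subj_group$group)
  gmeans <- tapply(d$value, d$group, mean)
  smeans <- tapply(d$value, d$session, mean)
  n_subj <- nrow(subj_group)
  lsd <- list()
  gl <- levels(d$group)
  for (i in seq_along(gl)) for (j in seq_along(gl)) if (i < j) {
    se <- sqrt(err_b[["Mean Sq"]] *
                 (1 / (n_per_group[[gl[i]]] * n_sess) +
                  1 / (n_per_group[[gl[j]]] * n_sess)))
    diff <- gmeans[[gl[i]]] - gmeans[[gl[j]]]
    tv <- if (se > 0) diff / se else if (abs(diff) < 1e-12) 0 else NA_real_
    lsd[[length(lsd) + 1L]] <- data.frame(
      factor = "group", level_1 = gl[i], level_2 = gl[j],
      diff = diff, t = tv, df = err_b[["Df"]],
      p = if (is.na(tv)) NA_real_ else
        2 * stats::pt(abs(tv), err_b[["Df"]], lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  sl <- levels(d$session)
  for (i in seq_along(sl)) for (j in seq_along(sl)) if (i < j) {
    se <- sqrt(err_w[["Mean Sq"]] * 2 / n_subj)
    diff <- smeans[[sl[i]]] - smeans[[sl[j]]]
    tv <- if (se > 0) diff / se else if (abs(diff) < 1e-12) 0 else NA_real_
    lsd[[length(lsd) + 1L]] <- data.frame(
      factor = "session", level_1 = sl[i], level_2 = sl[j],
      diff = diff, t = tv, df = err_w[["Df"]],
      p = if (is.na(tv)) NA_real_ else
        2 * stats::pt(abs(tv), err_w[["Df"]], lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  structure(list(anova_table = anova_table,
                 post_hoc = do.call(rbind, lsd),
                 fit = fit),
            class = "rm_anova")
}

#' PCA with varimax rotation and eigenvalue-greater-than-1 retention
#'
#' Principal component analysis of the correlation matrix of standardized
#' behavioral variables. Components with eigenvalue > 1 are retained and
#' their loadings varimax-rotated (normalized Kaiser variant, convergence
#' tolerance 1e-8). Explained-variance percentages are reported from the
#' unrotated eigenvalues; rotated sums of squared loadings are also
#' returned. Loadings are sign-fixed so each component's largest-magnitude
#' loading is positive.
#'
#' @param data Numeric data.frame/matrix, subjects x variables, complete
#'   cases only; requires at least 2 more subjects than variables.
#' @return A list of class `pca_result`: `eigenvalues`,
#'   `explained_variance_pct` (all components, sums to 100),
#'   `retained_components`, `loadings` (variables x retained, rotated),
#'   `unrotated_loadings`, `rotated_ss_pct`, `communalities`.
#' @export
pca_varimax <- function(data) {
  X <- as.matrix(as.data.frame(data))
  if (anyNA(X)) stop("complete cases required for PCA", call. = FALSE)
  n <- nrow(X); k <- ncol(X)
  if (n < k + 2L) stop("need at least 2 more subjects than variables",
                       call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    pairs <- which(abs(R) > 1 - 1e-8 & upper.tri(R), arr.ind = TRUE)
    coll <- apply(pairs, 1L, function(ij) {
      paste(colnames(R)[ij[1L]], "~", colnames(R)[ij[2L]])
    })
    stop("singular correlation matrix; collinear variables: ",
         if (length(coll)) paste(coll, collapse = ", ") else "(not pairwise)",
         call. = FALSE)
  }
  vals <- e$values
  retained <- sum(vals > 1)
  if (retained < 1L) retained <- 1L  # degenerate isotropic case: keep PC1
  L <- e$vectors[, seq_len(retained), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(retained)]), retained)
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(retained))
  Lr <- if (retained >= 2L) {
    rot <- stats::varimax(L, normalize = TRUE, eps = 1e-8)
    unclass(rot$loadings)
  } else L
  ## deterministic sign convention
  for (j in seq_len(ncol(Lr))) {
    if (Lr[which.max(abs(Lr[, j])), j] < 0) Lr[, j] <- -Lr[, j]
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  dimnames(Lr) <- dimnames(L)
  structure(list(
    eigenvalues = vals,
    explained_variance_pct = 100 * vals / sum(vals),
    retained_components = retained,
    loadings = Lr,
    unrotated_loadings = L,
    rotated_ss_pct = 100 * colSums(Lr^2) / k,
    communalities = rowSums(Lr^2)
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d/%d components retained (eigenvalue > 1)\n",
              x$retained_components, length(x$eigenvalues)))
  cat("  explained variance (unrotated): ",
      paste(sprintf("%.1f%%", x$explained_variance_pct[
        seq_len(x$retained_components)]), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}
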