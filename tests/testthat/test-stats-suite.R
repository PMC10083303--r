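test_that("the normality gate routes between Student's t and Mann-Whitney", {
  set.seed(1)
  x <- stats::rnorm(15); y <- stats::rnorm(15, 0.5)
  res <- compare_groups(x, y)
  expect_equal(res$test_name, "student_t")
  expect_true(all(res$normality_p_values >= 0.05))

  # heavy-tailed samples fail the Lilliefors gate
  set.seed(2)
  xs <- stats::rlnorm(30, 0, 2); ys <- stats::rlnorm(30, 0, 2)
  res2 <- compare_groups(xs, ys)
  expect_equal(res2$test_name, "mann_whitney_u")

  # routing is a pure function of the two KS p-values and alpha
  res3 <- compare_groups(x, y, alpha_normality = max(res$normality_p_values) + 0.01)
  expect_equal(res3$test_name, "mann_whitney_u")

  # degenerate zero-variance sample: Mann-Whitney with a warning
  expect_warning(res4 <- compare_groups(rep(1, 5), c(1, 2, 3, 4, 5)),
                 "degenerate")
  expect_equal(res4$test_name, "mann_whitney_u")

  expect_error(compare_groups(1:2, 1:5), "n >= 3")
})

test_that("identical and fully separated samples sit at the U extremes", {
  set.seed(3)
  x <- stats::rlnorm(8, 0, 2)
  expect_warning(res <- compare_groups(x, x), regexp = NA)
  if (res$test_name == "mann_whitney_u") {
    expect_equal(res$statistic, length(x)^2 / 2)  # null center n1*n2/2
  }
  expect_gt(res$p_value, 0.9)

  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
})

test_that("U equals the brute-force discordant-pair count for n <= 12", {
  u_brute <- function(x, y) {
    s <- 0
    for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
    min(s, length(x) * length(y) - s)
  }
  set.seed(4)
  for (rep in 1:120) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    if (rep %% 3 == 0) {  # discrete data with ties
      x <- sample(0:5, n1, replace = TRUE)
      y <- sample(0:5, n2, replace = TRUE)
    } else {
      x <- stats::rnorm(n1); y <- stats::rnorm(n2, 0.3)
    }
    expect_equal(mann_whitney_u(x, y)$U, u_brute(x, y))
  }
})

test_that("exact Mann-Whitney p-values match the null distribution", {
  # n1 = n2 = 3, complete separation: one-tailed prob 1/C(6,3) = 1/20
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 2 / 20)
})

test_that("chi-square matches its closed forms and symmetries", {
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)

  # perfect association: statistic = N
  res <- chi_square_2x2(matrix(c(20, 0, 0, 20), 2))
  expect_equal(res$statistic, 40)
  expect_equal(res$df, 1)

  # direct-formula oracle and invariance under transpose / swaps
  chisq_brute <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  set.seed(5)
  for (rep in 1:50) {
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
    got <- suppressWarnings(chi_square_2x2(tab)$statistic)
    expect_equal(got, chisq_brute(tab))
    suppressWarnings({
      expect_equal(chi_square_2x2(t(tab))$statistic, got)
      expect_equal(chi_square_2x2(tab[2:1, ])$statistic, got)
      expect_equal(chi_square_2x2(tab[, 2:1])$statistic, got)
    })
  }

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("correlation matrices handle exact (anti)linearity and NA policy", {
  d <- data.frame(a = c(1, 2, 3), b = c(2, 4, 6), c = c(6, 4, 2))
  cm <- pearson_correlation_matrix(d)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(cm$r >= -1 & cm$r <= 1, na.rm = TRUE))

  # zero-variance variable: its pairs are reported as absent
  d2 <- data.frame(a = c(1, 2, 3, 4), z = c(5, 5, 5, 5))
  cm2 <- pearson_correlation_matrix(d2)
  expect_true(is.na(cm2$r["a", "z"]))
  expect_true(is.na(cm2$r["z", "z"]))

  # pairwise-complete n bookkeeping
  d3 <- data.frame(a = c(1, 2, 3, NA, 5), b = c(2, 1, 4, 3, NA))
  cm3 <- pearson_correlation_matrix(d3)
  expect_equal(cm3$n["a", "b"], 3L)
})

test_that("mixed-design RM-ANOVA agrees with a sums-of-squares oracle", {
  # 2 groups x 2 subjects x 3 sessions, hand-decomposable
  d <- expand.grid(subject = paste0("s", 1:4), session = paste0("t", 1:3),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% c("s1", "s2"), "g1", "g2")
  set.seed(6)
  d$value <- c(2, 3, 5, 7, 4, 6, 8, 11, 6, 8, 12, 14)

  res <- rm_anova(d)

  # independent decomposition
  S <- 3; grand <- mean(d$value)
  subj_means <- tapply(d$value, d$subject, mean)
  grp_of <- c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2")
  grp_means <- tapply(d$value, d$group, mean)
  sess_means <- tapply(d$value, d$session, mean)
  cell_means <- tapply(d$value, list(d$group, d$session), mean)
  ss_between <- S * sum((subj_means - grand)^2)
  ss_group <- S * 2 * sum((grp_means - grand)^2)
  ss_subj_wg <- ss_between - ss_group
  ss_within <- sum((d$value - subj_means[d$subject])^2)
  ss_sess <- 4 * sum((sess_means - grand)^2)
  ss_int <- 2 * sum((sweep(sweep(cell_means, 1, grp_means), 2, sess_means) +
                       grand)^2)
  ss_err <- ss_within - ss_sess - ss_int
  f_group <- (ss_group / 1) / (ss_subj_wg / 2)
  f_sess <- (ss_sess / 2) / (ss_err / 4)
  f_int <- (ss_int / 2) / (ss_err / 4)

  tab <- res$anova_table
  expect_equal(tab$F[tab$effect == "group"], f_group, tolerance = 1e-10)
  expect_equal(tab$F[tab$effect == "session"], f_sess, tolerance = 1e-10)
  expect_equal(tab$F[tab$effect == "group:session"], f_int, tolerance = 1e-10)
  expect_equal(tab$df1, c(1, 2, 2))
  expect_equal(tab$df2, c(2, 4, 4))

  # Fisher LSD group contrast uses the between-subject error term
  lsd <- res$post_hoc
  g_row <- lsd[lsd$factor == "group", ]
  se <- sqrt((ss_subj_wg / 2) * (1 / 6 + 1 / 6))
  expect_equal(g_row$t, (grp_means[["g1"]] - grp_means[["g2"]]) / se,
               tolerance = 1e-10)
  expect_equal(g_row$df, 2)
  expect_equal(nrow(lsd[lsd$factor == "session", ]), 3L)
})

test_that("degenerate RM-ANOVA inputs behave as specified", {
  d <- expand.grid(subject = paste0("s", 1:4), session = paste0("t", 1:3),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% c("s1", "s2"), "g1", "g2")

  # all responses identical: all F = 0
  d$value <- 5
  res <- rm_anova(d)
  expect_equal(res$anova_table$F, c(0, 0, 0))
  expect_equal(res$anova_table$p, c(1, 1, 1))

  # identical group trajectories: group effect F = 0, p = 1
  d$value <- rep(c(1, 2, 3), each = 4)
  res2 <- rm_anova(d)
  expect_equal(res2$anova_table$F[res2$anova_table$effect == "group"], 0)
  expect_gt(res2$anova_table$F[res2$anova_table$effect == "session"], 0)

  # missing cells are an error, not an imputation
  expect_error(rm_anova(d[-1, ]), "missing cells")
})

test_that("PCA retains eigenvalue > 1 components and varimax preserves structure", {
  # two perfectly correlated variables: singular, named in the error
  d <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = 2 * c(1, 2, 3, 4, 5, 6) + 1)
  expect_error(pca_varimax(d), "collinear|singular")

  # two almost perfectly correlated variables: one component carries ~all
  set.seed(10)
  a <- stats::rnorm(30)
  d1 <- data.frame(a = a, b = a + 0.01 * stats::rnorm(30))
  p1 <- pca_varimax(d1)
  expect_equal(p1$retained_components, 1L)
  expect_gt(p1$explained_variance_pct[1], 99)

  # near-isotropic data: eigenvalues ~ 1, loadings unchanged up to sign
  set.seed(8)
  iso <- as.data.frame(matrix(stats::rnorm(4000), ncol = 4))
  p_iso <- pca_varimax(iso)
  expect_true(all(abs(p_iso$eigenvalues - 1) < 0.2))
  expect_equal(sum(p_iso$eigenvalues), 4, tolerance = 1e-9)

  # planted two-factor structure in 7 variables
  set.seed(9)
  n <- 40
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  X <- data.frame(
    v1 = f1 + 0.3 * stats::rnorm(n), v2 = f1 + 0.3 * stats::rnorm(n),
    v3 = f1 + 0.3 * stats::rnorm(n), v4 = f2 + 0.3 * stats::rnorm(n),
    v5 = f2 + 0.3 * stats::rnorm(n), v6 = stats::rnorm(n),
    v7 = stats::rnorm(n))
  p <- pca_varimax(X)
  expect_gte(p$retained_components, 2L)
  expect_equal(sum(p$explained_variance_pct), 100, tolerance = 1e-6)
  expect_equal(sum(p$eigenvalues), 7, tolerance = 1e-9)
  expect_identical(p$retained_components, sum(p$eigenvalues > 1))

  # communality preservation under rotation, to 1e-9
  h_rot <- rowSums(p$loadings^2)
  h_unrot <- rowSums(p$unrotated_loadings^2)
  expect_lt(max(abs(h_rot - h_unrot)), 1e-9)

  # sign convention: every component's largest-magnitude loading is positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }

  expect_error(pca_varimax(X[1:6, ]), "more subjects than variables")
})
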