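# Group-comparison statistics for the clinical covariate table: one-way
# ANOVA (raw and from printed summaries), Welch ANOVA, Pearson chi-square,
# Mann-Whitney U, Kendall tau, one-way ANCOVA, and the assembled
# group-comparison report. No multiplicity correction is applied anywhere;
# per-covariate results are reported as-is.

test_result <- function(statistic, value, df, p) {
  structure(list(statistic = statistic, value = unname(value),
                 df = unname(df), p = unname(p)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, df = %s, p = %.4g\n", x$statistic, x$value,
              paste(signif(x$df, 6), collapse = ", "), x$p))
  invisible(x)
}

#' One-way ANOVA
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return `test_result` with F, df (between, within), p.
#' @export
one_way_anova <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  assert_that(all(vapply(groups, length, 1L) >= 2), "each group needs >= 2 values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups); n <- length(y)
  msb <- sum(tapply(y, g, length) * (tapply(y, g, mean) - mean(y))^2) / (k - 1)
  msw <- sum((y - stats::ave(y, g))^2) / (n - k)
  f <- if (msw == 0 && msb == 0) 0 else msb / msw
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  test_result("F", f, c(k - 1, n - k), p)
}

#' Two-group ANOVA from summary statistics
#'
#' Recomputes the one-way F from reported means, SDs and group sizes:
#' `SSB = sum n_i (m_i - grand)^2`, `MSW = sum (n_i - 1) sd_i^2 / (N - 2)`,
#' `F = SSB / MSW` on (1, N - 2) df. Identical to [one_way_anova()] applied
#' to any raw data having those summaries.
#'
#' @param m1,sd1,n1,m2,sd2,n2 per-group mean, SD and size.
#' @return `test_result`.
#' @export
anova_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  assert_that(n1 >= 2 && n2 >= 2, "need n >= 2 per group")
  assert_that(sd1 >= 0 && sd2 >= 0, "SDs must be non-negative")
  n <- n1 + n2
  grand <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  msw <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n - 2)
  if (msw == 0) {
    f <- if (ssb > 0) Inf else 0
    if (ssb > 0) warnf("zero within-group variance with distinct means: F infinite")
  } else f <- ssb / msw
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  test_result("F", f, c(1, n - 2), p)
}

#' Welch ANOVA (two groups)
#'
#' `F = (mean(x) - mean(y))^2 / (s_x^2/n_x + s_y^2/n_y)` with df1 = 1 and
#' Welch-Satterthwaite df2; equals the squared Welch t.
#'
#' @param x,y numeric vectors, each >= 2 values with positive variance.
#' @return `test_result`.
#' @export
welch_anova <- function(x, y) {
  assert_that(length(x) >= 2 && length(y) >= 2, "each group needs >= 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  assert_that(vx > 0 && vy > 0, "zero within-group variance")
  res <- welch_anova_from_summary(mean(x), sqrt(vx), length(x),
                                  mean(y), sqrt(vy), length(y))
  res
}

#' Welch ANOVA from summary statistics
#'
#' @param m1,sd1,n1,m2,sd2,n2 per-group mean, SD and size.
#' @return `test_result`.
#' @export
welch_anova_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  assert_that(sd1 > 0 && sd2 > 0, "zero within-group variance")
  se1 <- sd1^2 / n1; se2 <- sd2^2 / n2
  f <- (m1 - m2)^2 / (se1 + se2)
  df2 <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  test_result("F", f, c(1, df2), p)
}

#' Pearson chi-square test of association
#'
#' No continuity correction; expected counts from the margins.
#'
#' @param table 2D non-negative contingency matrix with positive margins.
#' @return `test_result` with chi-square, df = (r-1)(c-1), p.
#' @export
chi_square <- function(table) {
  tab <- as.matrix(table)
  assert_that(length(dim(tab)) == 2 && all(tab >= 0), "need a non-negative 2D table")
  assert_that(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
              "table has a zero margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result("chi-square", res$statistic, res$parameter, res$p.value)
}

#' Mann-Whitney U test
#'
#' Reports `U = min(U_x, U_y)` with midrank ties. P-value: exact (via the
#' Wilcoxon distribution) for small samples without ties, otherwise the
#' tie-corrected normal approximation, two-sided.
#'
#' @param x,y numeric vectors.
#' @param exact_max use the exact distribution when `n_x + n_y` is at most
#'   this and there are no ties (default 50).
#' @return `test_result` with U; `df` is `c(n_x, n_y)` for reference.
#' @export
mann_whitney_u <- function(x, y, exact_max = 50) {
  assert_that(length(x) >= 1 && length(y) >= 1, "both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  u <- min(ux, uy)
  ties <- any(duplicated(c(x, y)))
  if (!ties && nx + ny <= exact_max) {
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE)$p.value)
  }
  test_result("U", u, c(nx, ny), p)
}

#' Kendall tau-b correlation test
#'
#' Tau-b with tie correction; p from the normal approximation of the
#' statistic's null variance.
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @return `test_result` with tau; `df` is n.
#' @export
kendall_tau <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3, "need >= 3 pairs")
  assert_that(stats::var(x) > 0 && stats::var(y) > 0,
              "Kendall tau undefined for a constant vector")
  res <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                          exact = FALSE))
  test_result("tau", res$estimate, length(x), res$p.value)
}

#' One-way ANCOVA
#'
#' Linear model `y ~ group + covariate`; partial F tests for each term
#' (each on 1 and n - 3 df; type-III, which for this two-term additive
#' model equals the squared coefficient t).
#'
#' @param y response.
#' @param group two-level grouping factor/vector.
#' @param covariate numeric covariate (non-constant).
#' @return list with `group` and `covariate` `test_result`s and the fitted
#'   `model`.
#' @export
ancova <- function(y, group, covariate) {
  group <- factor(group)
  assert_that(nlevels(group) == 2, "group must have exactly 2 levels")
  assert_that(stats::var(covariate) > 0, "covariate is constant")
  n <- length(y)
  assert_that(n >= 5, "need n >= 5 observations")
  if (stats::var(y) == 0) {
    # constant response: no variance to attribute to either term
    zero <- test_result("F", 0, c(1, n - 3), 1)
    return(list(group = zero, covariate = zero,
                model = stats::lm(y ~ group + covariate)))
  }
  fit <- stats::lm(y ~ group + covariate)
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 3) stopf("covariate is collinear with the group indicator")
  f_group <- sm[2, "t value"]^2
  f_cov <- sm[3, "t value"]^2
  df2 <- fit$df.residual
  list(group = test_result("F", f_group, c(1, df2),
                           stats::pf(f_group, 1, df2, lower.tail = FALSE)),
       covariate = test_result("F", f_cov, c(1, df2),
                               stats::pf(f_cov, 1, df2, lower.tail = FALSE)),
       model = fit)
}

#' Clinical group-comparison report
#'
#' Applies the designated test per covariate between two subject groups
#' (e.g. marker-positive vs marker-negative): `anova` or `welch` for
#' continuous covariates (reported as mean (SD)), `mannwhitney` for skewed
#' ones (reported as medians), `chisq` for categorical ones (reported as
#' level counts). Covariates entirely missing in one group are skipped
#' with a `message()`. Results carry no multiplicity correction.
#'
#' @param clin clinical data.frame with a `group` column (two levels).
#' @param tests named character vector covariate -> test
#'   (`"anova"`, `"welch"`, `"mannwhitney"`, `"chisq"`).
#' @param group_col name of the grouping column (default `"group"`).
#' @return data.frame: covariate, test, summary per group, statistic, df,
#'   p.
#' @export
group_comparison_table <- function(clin, tests, group_col = "group") {
  assert_that(group_col %in% names(clin), "no '%s' column", group_col)
  g <- factor(clin[[group_col]])
  assert_that(nlevels(g) == 2, "grouping column must have two levels")
  lv <- levels(g)
  rows <- list()
  for (cv in names(tests)) {
    if (!cv %in% names(clin)) {
      message(sprintf("covariate '%s' absent, skipped", cv)); next
    }
    v <- clin[[cv]]
    v1 <- v[g == lv[1]]; v2 <- v[g == lv[2]]
    if (all(is.na(v1)) || all(is.na(v2))) {
      message(sprintf("covariate '%s' missing in one group, skipped", cv)); next
    }
    type <- tests[[cv]]
    res <- switch(type,
      anova = anova_from_summary(mean(v1, na.rm = TRUE), stats::sd(v1, na.rm = TRUE),
                                 sum(!is.na(v1)),
                                 mean(v2, na.rm = TRUE), stats::sd(v2, na.rm = TRUE),
                                 sum(!is.na(v2))),
      welch = welch_anova(v1[!is.na(v1)], v2[!is.na(v2)]),
      mannwhitney = mann_whitney_u(v1[!is.na(v1)], v2[!is.na(v2)]),
      chisq = chi_square(table(g, v)),
      stopf("unknown test type '%s' for covariate '%s'", type, cv))
    summarize <- function(vv) {
      if (type == "chisq") paste(table(factor(vv)), collapse = ":")
      else if (type == "mannwhitney")
        sprintf("Mdn %.2f", stats::median(vv, na.rm = TRUE))
      else sprintf("%.2f (%.2f)", mean(vv, na.rm = TRUE), stats::sd(vv, na.rm = TRUE))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cv, test = type,
      group1 = summarize(v1), group2 = summarize(v2),
      statistic = res$statistic, value = res$value,
      df = paste(signif(res$df, 6), collapse = ", "),
      p = res$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
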