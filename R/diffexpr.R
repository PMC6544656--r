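# Empirical-Bayes moderated t-test between case and control groups, fold
# changes, and the ranked differential-expression table.
#
# The gene-wise sample variances s_g^2 (residual df d_g) are modelled as
# scaled inverse-chi-square draws around a prior variance s0^2 with prior df
# d0. The prior is estimated by the log-variance moment method: on
# z_g = log(s_g^2), E[z] and Var[z] involve digamma/trigamma functions of
# d_g/2 and d0/2, so matching moments and inverting the trigamma gives d0,
# then s0^2 from the location equation. The moderated statistic replaces
# s_g^2 with the posterior variance (d0 s0^2 + d_g s_g^2) / (d0 + d_g) and
# gains d0 extra degrees of freedom.

#' Construct a variance prior
#'
#' @param d0 prior degrees of freedom (> 0; may be `Inf`).
#' @param s0_sq prior variance (> 0).
#' @return object of class `variance_prior`.
#' @export
variance_prior <- function(d0, s0_sq) {
  assert_that(length(d0) == 1 && d0 > 0, "d0 must be positive (possibly Inf)")
  assert_that(length(s0_sq) == 1 && is.finite(s0_sq) && s0_sq > 0,
              "s0_sq must be positive and finite")
  structure(list(d0 = as.numeric(d0), s0_sq = as.numeric(s0_sq)),
            class = "variance_prior")
}

# Newton inversion of trigamma(y) = x for x > 0 (monotone decreasing).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Estimate the variance prior from gene-wise sample variances
#'
#' Moment estimator on the log scale: with `e_g = log(s_g^2) -
#' digamma(d_g/2) + log(d_g/2)`, the excess dispersion of `e_g` beyond
#' `trigamma(d_g/2)` estimates `trigamma(d0/2)`; if there is no excess
#' dispersion the prior df is infinite and `s0_sq` is the mean sample
#' variance.
#'
#' @param s_sq per-gene sample variances (> 0).
#' @param d residual degrees of freedom, scalar or per-gene vector.
#' @return a [variance_prior()].
#' @export
estimate_variance_prior <- function(s_sq, d) {
  ok <- is.finite(s_sq) & s_sq > 0 & d >= 1
  s_sq <- s_sq[ok]
  if (length(d) > 1) d <- d[ok]
  n <- length(s_sq)
  if (n < 2) stopf("prior not estimable: need >= 2 genes with positive variance")
  if (length(d) == 1) d <- rep(d, n)

  e <- log(s_sq) - digamma(d / 2) + log(d / 2)
  e_mean <- mean(e)
  # unbiased dispersion of e minus the expected within-gene component
  excess <- mean((e - e_mean)^2 * n / (n - 1) - trigamma(d / 2))
  if (excess <= 0) {
    # no excess dispersion: the gene variances are exchangeable draws from
    # a single value, estimated by their arithmetic mean
    return(variance_prior(Inf, mean(s_sq)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  variance_prior(d0, s0_sq)
}

#' Moderated t-test for a two-group comparison
#'
#' Per gene: pooled two-group variance with `d_g = n1 + n2 - 2` residual df,
#' posterior variance `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` (reducing to
#' `s0^2` for infinite `d0`, and to the ordinary pooled t when `d0 = 0`),
#' moderated statistic and two-sided p-value on `d0 + d_g` df (normal when
#' infinite).
#'
#' @param m genes x samples matrix (log2 scale, typically preprocessed).
#' @param traits sample traits (`sample_id`, `group`).
#' @param prior a [variance_prior()], or any list with fields `d0` (>= 0;
#'   `d0 = 0` gives the ordinary pooled two-sample t) and `s0_sq`.
#' @return data.frame of class `de_result`: gene, mean_case, mean_control,
#'   log2fc, fold_change (linear magnitude >= 1), direction (`up`/`down`),
#'   s_sq, t, df, p.
#' @export
moderated_t <- function(m, traits, prior) {
  check_expression_matrix(m)
  check_traits(traits, m)
  assert_that(!is.null(prior$d0) && !is.null(prior$s0_sq) && prior$d0 >= 0,
              "prior must provide d0 >= 0 and s0_sq")
  ctrl <- intersect(colnames(m), traits$sample_id[traits$group == "control"])
  case <- intersect(colnames(m), traits$sample_id[traits$group == "case"])
  n1 <- length(case); n2 <- length(ctrl)
  assert_that(n1 >= 2 && n2 >= 2, "both groups need >= 2 samples")

  mean_case <- rowMeans(m[, case, drop = FALSE])
  mean_ctrl <- rowMeans(m[, ctrl, drop = FALSE])
  ss_case <- rowSums((m[, case, drop = FALSE] - mean_case)^2)
  ss_ctrl <- rowSums((m[, ctrl, drop = FALSE] - mean_ctrl)^2)
  d_g <- n1 + n2 - 2
  s_sq <- (ss_case + ss_ctrl) / d_g

  if (is.infinite(prior$d0)) {
    s_tilde_sq <- rep(prior$s0_sq, nrow(m))
    df <- Inf
  } else {
    s_tilde_sq <- (prior$d0 * prior$s0_sq + d_g * s_sq) / (prior$d0 + d_g)
    df <- prior$d0 + d_g
  }
  lfc <- mean_case - mean_ctrl
  t_mod <- lfc / sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
  p <- if (is.infinite(df)) 2 * stats::pnorm(-abs(t_mod))
       else 2 * stats::pt(-abs(t_mod), df)

  out <- data.frame(gene = rownames(m),
                    mean_case = mean_case,
                    mean_control = mean_ctrl,
                    log2fc = lfc,
                    fold_change = 2^abs(lfc),
                    direction = ifelse(lfc >= 0, "up", "down"),
                    s_sq = s_sq,
                    t = t_mod,
                    df = df,
                    p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Ranked differential-expression table
#'
#' Keeps genes with `p <= p_threshold` and `fold_change >= fc_cutoff`,
#' sorted by fold change descending. No multiple-testing adjustment is
#' applied (deliberately: the screening design treats the p threshold as a
#' per-gene filter).
#'
#' @param res a [moderated_t()] result.
#' @param p_threshold per-gene significance threshold (default 0.01).
#' @param fc_cutoff minimum linear fold-change magnitude (default 1.0).
#' @return filtered, sorted data.frame.
#' @export
de_table <- function(res, p_threshold = 0.01, fc_cutoff = 1.0) {
  assert_that(inherits(res, "data.frame") && all(c("p", "fold_change") %in% names(res)),
              "res must be a moderated_t() result")
  assert_that(p_threshold > 0 && p_threshold <= 1, "p_threshold must be in (0,1]")
  assert_that(fc_cutoff >= 1, "fc_cutoff must be >= 1")
  keep <- res$p <= p_threshold & res$fold_change >= fc_cutoff
  out <- res[keep, , drop = FALSE]
  out <- out[order(-out$fold_change, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
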