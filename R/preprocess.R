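# Gene-level preprocessing: background expression filter, quantile
# normalization, median baseline transformation.

#' Background expression filter
#'
#' Keeps genes whose signal lies at or above the `lower_pct` percentile of
#' their own array's value distribution in all replicates of at least one of
#' the two groups. The percentile is computed per sample over all genes with
#' linear interpolation between order statistics (inclusive endpoints). The
#' filter is meant for the raw (pre-normalization) matrix.
#'
#' @param raw genes x samples matrix of non-negative raw-scale (or log-scale)
#'   intensities.
#' @param traits sample trait data.frame (`sample_id`, `group`).
#' @param lower_pct lower percentile bound, default 20.
#' @return character vector of retained gene IDs.
#' @export
background_filter <- function(raw, traits, lower_pct = 20) {
  check_expression_matrix(raw, "raw matrix")
  check_traits(traits, raw)
  assert_that(all(raw >= 0), "raw matrix must be non-negative")
  assert_that(lower_pct >= 0 && lower_pct <= 100, "lower_pct must be in [0,100]")
  thr <- apply(raw, 2, stats::quantile, probs = lower_pct / 100,
               type = 7, names = FALSE)
  above <- sweep(raw, 2, thr, ">=")
  keep <- rep(FALSE, nrow(raw))
  for (g in c("control", "case")) {
    cols <- traits$sample_id[traits$group == g]
    cols <- intersect(colnames(raw), cols)
    assert_that(length(cols) > 0, "group '%s' has no samples in the matrix", g)
    keep <- keep | apply(above[, cols, drop = FALSE], 1, all)
  }
  rownames(raw)[keep]
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the common distribution of row-rank
#' means: after normalization each column holds the identical sorted value
#' multiset, within-column ranks are preserved, and ties receive the average
#' of the reference values over the tied ranks.
#'
#' @param m genes x samples numeric matrix.
#' @return normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(m) {
  check_expression_matrix(m)
  if (ncol(m) < 2) {
    warnf("quantile_normalize: single sample, returning input unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Baseline transformation to the per-gene median
#'
#' Subtracts each gene's across-sample median, so every gene row of the
#' output has median zero (GeneSpring-style "baseline to median of all
#' samples" on log2 data).
#'
#' @param m genes x samples log2-scale matrix.
#' @return transformed matrix.
#' @export
baseline_transform <- function(m) {
  check_expression_matrix(m)
  med <- apply(m, 1, stats::median)
  sweep(m, 1, med, "-")
}

#' Drop zero-variance genes
#'
#' Genes with zero variance across samples have no defined correlation and
#' are removed before any network step; removals are reported via `message()`.
#'
#' @param m genes x samples matrix.
#' @return matrix restricted to genes with positive variance.
#' @export
drop_zero_variance <- function(m) {
  check_expression_matrix(m)
  v <- apply(m, 1, stats::var)
  zero <- v <= 0 | !is.finite(v)
  if (any(zero))
    message(sprintf("dropping %d zero-variance gene(s): %s", sum(zero),
                    paste(utils::head(rownames(m)[zero], 5), collapse = ", ")))
  m[!zero, , drop = FALSE]
}
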