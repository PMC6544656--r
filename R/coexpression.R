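# Unsigned weighted gene coexpression network: soft-threshold selection,
# adjacency A_mn = |cor(m,n)|^beta, topological overlap, module detection by
# average-linkage clustering on 1 - TOM with eigengene merging, and
# module-trait significance.

#' Pearson correlation matrix across samples
#'
#' @param m genes x samples matrix with >= 3 samples and no zero-variance
#'   genes.
#' @return symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(m) {
  check_expression_matrix(m)
  assert_that(ncol(m) >= 3, "need >= 3 samples for correlations")
  v <- apply(m, 1, stats::var)
  if (any(v <= 0))
    stopf("zero-variance gene(s): %s",
          paste(utils::head(rownames(m)[v <= 0], 5), collapse = ", "))
  cc <- stats::cor(t(m))
  diag(cc) <- 1
  cc
}

#' Soft-threshold adjacency
#'
#' Unsigned network adjacency `a_mn = |cor_mn|^beta`, diagonal set to 1.
#'
#' @param cor correlation matrix (entries in `[-1, 1]`).
#' @param beta soft-threshold exponent (> 0; the pipeline default is 6).
#' @return adjacency matrix with attribute `beta`.
#' @export
adjacency <- function(cor, beta = 6) {
  assert_that(length(beta) == 1 && is.finite(beta) && beta > 0,
              "beta must be positive")
  assert_that(max(abs(cor)) <= 1 + 1e-8, "correlations must lie in [-1,1]")
  a <- abs(cor)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Scale-free-topology soft-threshold selection
#'
#' For each candidate exponent, computes connectivities `k_i = sum_j a_ij`
#' (diagonal excluded), bins `log10(k)` into `n_bins` equal-width bins, and
#' regresses `log10(frequency)` on `log10(mean k per bin)`. The scale-free
#' fit index is the regression R^2, signed negative when the slope is
#' positive. Returns the smallest candidate whose fit reaches `r2_target`,
#' or the fit-maximizing candidate with a warning.
#'
#' @param m genes x samples matrix.
#' @param candidates candidate exponents.
#' @param r2_target target fit index (default 0.8).
#' @param n_bins connectivity histogram bins (default 10).
#' @return list with `beta` and `fit_table` (beta, fit, slope, mean_k,
#'   median_k, max_k).
#' @export
pick_soft_threshold <- function(m, candidates = c(1:10, 12, 14, 16, 18, 20),
                                r2_target = 0.8, n_bins = 10) {
  assert_that(length(candidates) > 0, "candidates must be non-empty")
  cc <- correlation_matrix(m)
  acor <- abs(cc)
  diag(acor) <- 0
  rows <- lapply(candidates, function(beta) {
    a <- acor^beta
    k <- rowSums(a)
    if (all(k <= 0)) stopf("all connectivities are zero at beta = %g", beta)
    fit <- scale_free_fit(k[k > 0], n_bins)
    data.frame(beta = beta, fit = fit$fit, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(tab$fit >= r2_target)
  if (length(hit) > 0) {
    beta <- tab$beta[hit[1]]
  } else {
    beta <- tab$beta[which.max(tab$fit)]
    warnf("no candidate reached fit %.2f; returning beta = %g (fit %.3f)",
          r2_target, beta, max(tab$fit))
  }
  list(beta = beta, fit_table = tab)
}

scale_free_fit <- function(k, n_bins = 10) {
  lk <- log10(k)
  breaks <- seq(min(lk), max(lk), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(lk, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(list(fit = NA_real_, slope = NA_real_))
  x <- log10(kmean[ok]); y <- log10(freq[ok])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(fit = if (slope > 0) -r2 else r2, slope = slope)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' diagonal 1. Shared-neighbour overlap augments direct adjacency, so two
#' genes are similar when they connect to the same part of the network even
#' if their direct adjacency is modest.
#'
#' @param a adjacency matrix (symmetric, unit diagonal, entries in `[0,1]`).
#' @return TOM with the same dimnames.
#' @export
topological_overlap <- function(a) {
  assert_that(is.matrix(a) && nrow(a) == ncol(a), "adjacency must be square")
  assert_that(max(abs(a - t(a))) < 1e-8, "adjacency must be symmetric")
  assert_that(min(a) >= -1e-12 && max(a) <= 1 + 1e-8,
              "adjacency entries must lie in [0,1]")
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Module eigengenes
#'
#' First principal component of each module's standardized expression
#' (genes scaled to zero mean, unit variance across samples), as a
#' unit-norm per-sample score, sign-oriented so the mean correlation with
#' the module's genes is non-negative. Columns are zero-mean across samples
#' by construction.
#'
#' @param expr genes x samples matrix.
#' @param modules named integer vector gene -> module label (0 = unassigned).
#' @return samples x modules matrix, columns named `ME<label>`.
#' @export
module_eigengenes <- function(expr, modules) {
  labs <- sort(unique(modules[modules > 0]))
  assert_that(length(labs) > 0, "no assigned modules")
  me <- sapply(labs, function(l) {
    genes <- names(modules)[modules == l]
    x <- t(expr[genes, , drop = FALSE])     # samples x genes
    x <- scale(x)
    if (ncol(x) == 1) {
      u <- x[, 1] / sqrt(sum(x[, 1]^2))
    } else {
      u <- svd(x, nu = 1, nv = 0)$u[, 1]
    }
    if (mean(stats::cor(u, x)) < 0) u <- -u
    u
  })
  me <- matrix(me, nrow = ncol(expr),
               dimnames = list(colnames(expr), paste0("ME", labs)))
  me
}

#' Detect coexpression modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, static tree cut at
#' `cut_height`, clusters below `min_module_size` set unassigned (label 0),
#' then iterative merging of module pairs whose eigengene dissimilarity
#' `1 - cor(ME_a, ME_b)` falls below `merge_cut_height` (closest pair
#' first), recomputing eigengenes after each merge. Final labels are
#' contiguous, ordered by decreasing module size.
#'
#' @param tom TOM from [topological_overlap()].
#' @param min_module_size minimum genes per module (default 20).
#' @param cut_height static cut height on 1 - TOM (default 0.99).
#' @param merge_cut_height eigengene-dissimilarity merge threshold
#'   (default 0.25).
#' @param expr the genes x samples matrix the TOM was built from (needed for
#'   eigengenes).
#' @return list with `modules` (named integer vector), `eigengenes`
#'   (samples x modules), `dendrogram` (hclust), `n_merged` (merge count).
#' @export
detect_modules <- function(tom, min_module_size = 20, cut_height = 0.99,
                           merge_cut_height = 0.25, expr) {
  assert_that(cut_height > 0 && cut_height < 1 + 1e-8 &&
                merge_cut_height > 0 && merge_cut_height < 1,
              "cut heights must lie in (0,1)")
  check_expression_matrix(expr)
  assert_that(all(rownames(tom) == rownames(expr)),
              "TOM and expression gene sets must match")
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  labels <- stats::cutree(hc, h = cut_height)
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  labels[labels %in% small] <- 0L
  labels <- relabel_modules(labels)
  names(labels) <- rownames(tom)
  if (all(labels == 0L)) {
    warnf("no cluster reached min_module_size; all genes unassigned")
    return(list(modules = labels, eigengenes = NULL, dendrogram = hc,
                n_merged = 0L))
  }

  n_merged <- 0L
  repeat {
    labs <- sort(unique(labels[labels > 0]))
    if (length(labs) < 2) break
    me <- module_eigengenes(expr, labels)
    d_me <- 1 - stats::cor(me)
    diag(d_me) <- Inf
    ij <- arrayInd(which.min(d_me), dim(d_me))
    if (d_me[ij] >= merge_cut_height) break
    a <- labs[ij[1]]; b <- labs[ij[2]]
    labels[labels == b] <- a
    labels <- relabel_modules(labels)
    n_merged <- n_merged + 1L
  }
  me <- module_eigengenes(expr, labels)
  list(modules = labels, eigengenes = me, dendrogram = hc, n_merged = n_merged)
}

#' Student-t p-value for a correlation coefficient
#'
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)`, two-sided p on `n - 2` df;
#' `|r| = 1` returns exactly 0.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param n sample count (>= 3).
#' @return p-value(s).
#' @export
cor_pvalue_student <- function(r, n) {
  assert_that(all(n >= 3), "need n >= 3")
  assert_that(all(abs(r) <= 1 + 1e-12), "|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) == 1, 0, {
    t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(t), n - 2)
  })
  unname(p)
}

#' Module-trait significance table
#'
#' Pearson correlation of each module eigengene with the binary trait
#' indicator (control = 0, case = 1), Student-t p-values, significance at
#' `alpha`, and the selected top module: the significant module with the
#' largest `|r|` (ties broken by lower p).
#'
#' @param me samples x modules eigengene matrix.
#' @param traits sample traits (`sample_id`, `group`).
#' @param alpha significance level (default 0.05).
#' @return list with `table` (module, r, p, significant), `top_module`
#'   (module name or `NA` if none significant), `n_modules`,
#'   `n_significant`.
#' @export
module_trait_table <- function(me, traits, alpha = 0.05) {
  assert_that(is.matrix(me) && !is.null(rownames(me)),
              "me must be a samples x modules matrix with sample rownames")
  check_traits(traits)
  y <- trait_indicator(traits, rownames(me))
  assert_that(stats::var(y) > 0, "trait is constant over these samples")
  n <- nrow(me)
  r <- as.numeric(stats::cor(me, y))
  p <- cor_pvalue_student(r, n)
  tab <- data.frame(module = colnames(me), r = r, p = p,
                    significant = p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  top <- NA_character_
  if (any(tab$significant)) {
    sig <- tab[tab$significant, , drop = FALSE]
    sig <- sig[order(-abs(sig$r), sig$p), , drop = FALSE]
    top <- sig$module[1]
  }
  list(table = tab, top_module = top,
       n_modules = nrow(tab), n_significant = sum(tab$significant))
}
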