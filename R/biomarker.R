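# Control-anchored marker panel: the 50%-of-control-mean detection rule,
# single and combined sensitivity/specificity, and the case-control
# differential Spearman correlation matrix.

#' Detection threshold from control values
#'
#' `threshold = fraction * arithmetic mean of the non-missing control
#' values`.
#'
#' @param control_values numeric vector of control relative expressions.
#' @param fraction multiplier of the control mean (default 0.5).
#' @return scalar threshold.
#' @export
marker_threshold <- function(control_values, fraction = 0.5) {
  v <- control_values[!is.na(control_values)]
  assert_that(length(v) >= 1, "no non-missing control values")
  assert_that(fraction > 0, "fraction must be positive")
  fraction * mean(v)
}

#' Classify samples with a thresholded marker panel
#'
#' Per marker a sample is detected iff its expression is strictly below
#' `fraction` times the control mean of that marker; the combination is
#' detected iff all member markers are detected (AND rule). "Positive"
#' means detected, so sensitivity = TP/(TP+FN) over cases and specificity
#' = TN/(TN+FP) over controls, both in percent. Samples missing any member
#' marker are excluded from that marker's (and the combination's)
#' denominator, with a `message()`.
#'
#' @param expr data.frame with `sample_id` and one column per marker
#'   (relative expression).
#' @param labels data.frame with `sample_id` and `group`
#'   (`control`/`case`).
#' @param markers markers forming the panel.
#' @param fraction threshold fraction of the control mean (default 0.5).
#' @return object of class `panel_result`: list with `thresholds`, `calls`
#'   (per-sample logical calls incl. `combination`), `performance`
#'   (marker/combination rows: TP, FP, TN, FN, sensitivity, specificity),
#'   `fraction`.
#' @export
classify_samples <- function(expr, labels, markers, fraction = 0.5) {
  assert_that(all(markers %in% names(expr)),
              "markers missing from expression table: %s",
              paste(setdiff(markers, names(expr)), collapse = ", "))
  assert_that(all(c("sample_id", "group") %in% names(labels)),
              "labels must have sample_id and group")
  grp <- labels$group[match(expr$sample_id, labels$sample_id)]
  assert_that(all(c("control", "case") %in% grp), "both groups required")

  thresholds <- vapply(markers, function(mk)
    marker_threshold(expr[[mk]][grp == "control"], fraction), numeric(1))

  calls <- data.frame(sample_id = expr$sample_id, group = grp,
                      stringsAsFactors = FALSE)
  for (mk in markers) calls[[mk]] <- expr[[mk]] < thresholds[[mk]]
  comb <- rep(TRUE, nrow(calls))
  for (mk in markers) comb <- comb & calls[[mk]]
  calls$combination <- comb
  n_miss <- sum(is.na(comb))
  if (n_miss > 0)
    message(sprintf("%d sample(s) missing a member marker, excluded from the combination", n_miss))

  perf_row <- function(det, name) {
    tp <- sum(det & grp == "case", na.rm = TRUE)
    fn <- sum(!det & grp == "case", na.rm = TRUE)
    fp <- sum(det & grp == "control", na.rm = TRUE)
    tn <- sum(!det & grp == "control", na.rm = TRUE)
    data.frame(marker = name, TP = tp, FP = fp, TN = tn, FN = fn,
               sensitivity = 100 * tp / (tp + fn),
               specificity = 100 * tn / (tn + fp),
               stringsAsFactors = FALSE)
  }
  perf <- do.call(rbind, c(lapply(markers, function(mk) perf_row(calls[[mk]], mk)),
                           list(perf_row(comb, "combination"))))
  rownames(perf) <- NULL
  structure(list(thresholds = thresholds, calls = calls, performance = perf,
                 fraction = fraction),
            class = "panel_result")
}

#' Spearman rank correlation with Student-t p-value
#'
#' Rho is the Pearson correlation of midranks (tie-corrected); the p-value
#' uses the Student-t approximation `t = rho sqrt(n-2)/sqrt(1-rho^2)` on
#' `n - 2` df (`|rho| = 1` gives p = 0).
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return list: rho, p, n.
#' @export
spearman_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "need >= 3 complete pairs")
  assert_that(stats::var(x) > 0 && stats::var(y) > 0,
              "Spearman correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p = cor_pvalue_student(rho, n), n = n)
}

#' Case-control differential Spearman correlation matrix
#'
#' For every marker pair, the Spearman correlation is computed within
#' controls and within cases; a correlation "appears" in a group iff its
#' p-value is below `alpha`. Pairs are then categorized: `both`,
#' `control_only` (lost in cases), `case_only` (gained in cases), or
#' `neither`. Pairs with fewer than 3 complete observations in a group get
#' missing statistics (category from the available flags, `neither` if
#' undecidable) with a `message()`.
#'
#' @param expr data.frame with `sample_id` and marker columns.
#' @param labels data.frame with `sample_id`, `group`.
#' @param markers markers to cross (default: all non-id columns).
#' @param alpha significance threshold (default 0.05).
#' @return data.frame: marker1, marker2, rho_control, p_control, rho_case,
#'   p_case, sign_control, sign_case, category.
#' @export
differential_correlation_matrix <- function(expr, labels, markers = NULL,
                                            alpha = 0.05) {
  if (is.null(markers))
    markers <- setdiff(names(expr), c("sample_id", "group"))
  assert_that(length(markers) >= 2, "need >= 2 markers")
  grp <- labels$group[match(expr$sample_id, labels$sample_id)]
  rows <- list()
  for (i in seq_len(length(markers) - 1)) {
    for (j in (i + 1):length(markers)) {
      st <- lapply(c("control", "case"), function(g) {
        xs <- expr[[markers[i]]][grp == g]
        ys <- expr[[markers[j]]][grp == g]
        ok <- !is.na(xs) & !is.na(ys)
        if (sum(ok) < 3) {
          message(sprintf("pair %s-%s: <3 complete pairs in %s",
                          markers[i], markers[j], g))
          return(list(rho = NA_real_, p = NA_real_))
        }
        spearman_correlation(xs, ys)
      })
      app <- vapply(st, function(s) !is.na(s$p) && s$p < alpha, logical(1))
      category <- if (app[1] && app[2]) "both"
      else if (app[1]) "control_only"
      else if (app[2]) "case_only"
      else "neither"
      rows[[length(rows) + 1L]] <- data.frame(
        marker1 = markers[i], marker2 = markers[j],
        rho_control = st[[1]]$rho, p_control = st[[1]]$p,
        rho_case = st[[2]]$rho, p_case = st[[2]]$p,
        sign_control = ifelse(is.na(st[[1]]$rho), NA, sign(st[[1]]$rho)),
        sign_case = ifelse(is.na(st[[2]]$rho), NA, sign(st[[2]]$rho)),
        category = category, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
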