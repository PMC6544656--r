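# qPCR relative quantification: housekeeping-gene normalization and
# per-plate calibrator anchoring (delta-delta-Ct with efficiency fixed at
# 2), plus the Ct-based expression-call filter.

check_ct_table <- function(ct) {
  need <- c("sample_id", "target", "ct", "plate_id", "role")
  assert_that(is.data.frame(ct) && all(need %in% names(ct)),
              "Ct table needs columns: %s", paste(need, collapse = ", "))
  assert_that(all(is.na(ct$ct) | ct$ct > 0), "Ct values must be positive or NA")
  assert_that(all(ct$role %in% c("sample", "calibrator")),
              "role must be 'sample' or 'calibrator'")
  invisible(ct)
}

# average technical replicates on the Ct scale
collapse_replicates <- function(ct) {
  agg <- stats::aggregate(ct["ct"],
                          by = ct[c("sample_id", "target", "plate_id", "role")],
                          FUN = function(x) mean(x, na.rm = TRUE))
  agg$ct[is.nan(agg$ct)] <- NA_real_
  if ("group" %in% names(ct)) {
    key <- paste(ct$sample_id, ct$plate_id)
    agg$group <- ct$group[match(paste(agg$sample_id, agg$plate_id), key)]
  }
  agg
}

#' Relative expression by delta-delta-Ct
#'
#' Per sample: `dCt = Ct(target) - Ct(housekeeping)`; per plate the same
#' quantity for the calibrator rows; `expression = 2^-(dCt_sample -
#' dCt_calibrator)`, so the calibrator is 1 on every plate and plate-wide
#' Ct shifts cancel. Technical replicates are averaged on the Ct scale
#' first. Samples with a missing target or housekeeping Ct get `NA` with a
#' `message()`; a plate lacking its calibrator is an error.
#'
#' @param ct Ct table (columns sample_id, target, ct, plate_id, role,
#'   optionally group).
#' @param target target gene name.
#' @param housekeeping housekeeping gene name.
#' @return data.frame: sample_id, plate_id, (group,) relative_expression.
#' @export
relative_expression <- function(ct, target, housekeeping) {
  check_ct_table(ct)
  assert_that(target %in% ct$target, "target '%s' absent from Ct table", target)
  assert_that(housekeeping %in% ct$target,
              "housekeeping gene '%s' absent from Ct table", housekeeping)
  agg <- collapse_replicates(ct)

  dct <- function(rows) {
    tg <- rows$ct[rows$target == target]
    hk <- rows$ct[rows$target == housekeeping]
    if (length(tg) != 1 || length(hk) != 1) return(NA_real_)
    tg - hk
  }
  plates <- unique(agg$plate_id[agg$role == "sample"])
  out <- list()
  for (pl in plates) {
    cal <- agg[agg$plate_id == pl & agg$role == "calibrator", , drop = FALSE]
    if (nrow(cal) == 0) stopf("plate '%s' has no calibrator rows", pl)
    cal_dct <- mean(vapply(split(cal, cal$sample_id), dct, numeric(1)),
                    na.rm = TRUE)
    if (!is.finite(cal_dct))
      stopf("plate '%s': calibrator lacks %s or %s Ct", pl, target, housekeeping)
    smp <- agg[agg$plate_id == pl & agg$role == "sample", , drop = FALSE]
    for (sid in unique(smp$sample_id)) {
      rows <- smp[smp$sample_id == sid, , drop = FALSE]
      d <- dct(rows)
      if (is.na(d))
        message(sprintf("sample '%s' (plate %s): missing Ct, expression set NA",
                        sid, pl))
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, plate_id = pl,
        group = if ("group" %in% names(rows)) rows$group[1] else NA_character_,
        relative_expression = 2^(-(d - cal_dct)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Marker expression table from a Ct table
#'
#' Applies [relative_expression()] to several targets and returns a wide
#' sample x marker table.
#'
#' @param ct Ct table.
#' @param targets character vector of target genes.
#' @param housekeeping housekeeping gene.
#' @return data.frame: sample_id, (group,) one column per target.
#' @export
marker_expression_table <- function(ct, targets, housekeeping) {
  per <- lapply(targets, function(tg) relative_expression(ct, tg, housekeeping))
  base <- unique(do.call(rbind, per)[c("sample_id", "group")])
  for (i in seq_along(targets)) {
    base[[targets[i]]] <-
      per[[i]]$relative_expression[match(base$sample_id, per[[i]]$sample_id)]
  }
  rownames(base) <- NULL
  base
}

#' Expression-call filter on raw Ct
#'
#' A sample is called expressed for the target iff its (replicate-averaged)
#' Ct is at most `ct_max`; Ct strictly above `ct_max` means no detectable
#' expression. Missing Ct yields `NA`.
#'
#' @param ct Ct table.
#' @param target target gene.
#' @param ct_max no-expression cutoff in cycles (default 29).
#' @return data.frame: sample_id, ct, expressed (logical).
#' @export
expression_call_filter <- function(ct, target, ct_max = 29) {
  check_ct_table(ct)
  agg <- collapse_replicates(ct)
  agg <- agg[agg$target == target & agg$role == "sample", , drop = FALSE]
  data.frame(sample_id = agg$sample_id, ct = agg$ct,
             expressed = ifelse(is.na(agg$ct), NA, agg$ct <= ct_max),
             row.names = NULL, stringsAsFactors = FALSE)
}
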