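# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == round(x)

#' @keywords internal
check_expression_matrix <- function(m, what = "expression matrix") {
  assert_that(is.matrix(m) && is.numeric(m), "%s must be a numeric matrix", what)
  assert_that(!is.null(rownames(m)) && !is.null(colnames(m)),
              "%s needs gene rownames and sample colnames", what)
  assert_that(!anyDuplicated(rownames(m)), "duplicate gene IDs in %s", what)
  assert_that(!anyDuplicated(colnames(m)), "duplicate sample IDs in %s", what)
  assert_that(all(is.finite(m)), "%s contains non-finite values", what)
  invisible(m)
}

#' @keywords internal
check_traits <- function(traits, m = NULL) {
  assert_that(is.data.frame(traits) &&
                all(c("sample_id", "group") %in% names(traits)),
              "traits must be a data.frame with sample_id and group columns")
  assert_that(all(traits$group %in% c("control", "case")),
              "trait group must be 'control' or 'case'")
  if (!is.null(m)) {
    missing <- setdiff(colnames(m), traits$sample_id)
    assert_that(length(missing) == 0L,
                "samples without trait rows: %s", paste(missing, collapse = ", "))
  }
  assert_that(all(c("control", "case") %in% traits$group),
              "both groups must be non-empty")
  invisible(traits)
}

# group indicator aligned to matrix columns: control = 0, case = 1
trait_indicator <- function(traits, sample_ids) {
  g <- traits$group[match(sample_ids, traits$sample_id)]
  as.numeric(g == "case")
}

# relabel a module vector so labels are contiguous 1..K by decreasing size,
# keeping 0 for unassigned
relabel_modules <- function(labels) {
  pos <- labels[labels > 0]
  if (length(pos) == 0L) return(labels)
  sizes <- sort(table(pos), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes), names(sizes))
  out <- labels
  out[labels > 0] <- map[as.character(pos)]
  out
}
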