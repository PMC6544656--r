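# Seeded synthetic-data generators emulating the statistical structure the
# downstream stages assume: a small two-group microarray-like expression
# matrix with planted coexpression modules, a two-group human cohort of
# marker relative-expression values with a planted low-expressing patient
# subset, and a clinical covariate table.

#' Configuration for the expression-matrix simulator
#'
#' Defines a genes x samples log2-intensity matrix with planted coexpressed
#' modules. Each module m has a latent factor per sample; case samples have
#' the factor shifted by `case_shift_per_module[m]` (in within-group SD units
#' of the factor; negative = down in cases). A gene in module m with loading
#' rho is `rho * factor + sqrt(1 - rho^2) * noise`; background genes are
#' independent Gaussian noise with SD `background_sd`. All values are offset
#' by `intensity_offset` so they sit on a microarray-like log2 scale.
#'
#' Defaults mirror the discovery design this package targets: 7 control and
#' 5 case samples, two planted 50-gene modules (one shifted down by 1.5 SD in
#' cases, one trait-neutral) among 2,000 genes.
#'
#' @param n_genes total number of genes.
#' @param n_control,n_case samples per group.
#' @param module_sizes integer vector of planted module sizes.
#' @param module_gene_loading_range range (lo, hi) in (0,1) that per-gene
#'   loadings are drawn from uniformly.
#' @param case_shift_per_module signed shift of each module's latent factor in
#'   case samples, one value per module.
#' @param background_sd SD (log2 units) of background-gene noise.
#' @param intensity_offset additive log2 offset (microarray-like scale).
#' @param seed integer seed; the generator is deterministic given the config.
#' @return an object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 2000L,
                            n_control = 7L,
                            n_case = 5L,
                            module_sizes = c(50L, 50L),
                            module_gene_loading_range = c(0.7, 0.95),
                            case_shift_per_module = c(-1.5, 0),
                            background_sd = 1,
                            intensity_offset = 8,
                            seed = 1L) {
  assert_that(is_count(n_genes) && n_genes >= 1, "n_genes must be a positive count")
  assert_that(is_count(n_control) && is_count(n_case), "group sizes must be counts")
  assert_that(n_control + n_case >= 4, "need at least 4 samples in total")
  assert_that(all(vapply(module_sizes, is_count, logical(1))) &&
                all(module_sizes >= 1), "module_sizes must be positive counts")
  assert_that(sum(module_sizes) <= n_genes,
              "sum(module_sizes) exceeds n_genes")
  lr <- module_gene_loading_range
  assert_that(length(lr) == 2 && all(lr > 0) && all(lr < 1) && lr[1] <= lr[2],
              "loading range must lie in (0,1)")
  assert_that(length(case_shift_per_module) == length(module_sizes),
              "one case shift per module required")
  assert_that(background_sd >= 0, "background_sd must be non-negative")
  structure(list(n_genes = as.integer(n_genes),
                 n_control = as.integer(n_control),
                 n_case = as.integer(n_case),
                 module_sizes = as.integer(module_sizes),
                 module_gene_loading_range = as.numeric(lr),
                 case_shift_per_module = as.numeric(case_shift_per_module),
                 background_sd = background_sd,
                 intensity_offset = intensity_offset,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate a two-group expression matrix with planted coexpression modules
#'
#' @param config an [expr_sim_config()].
#' @return list with `expr` (genes x samples log2 matrix), `traits`
#'   (data.frame: sample_id, group) and `truth` (list: `modules`, a named
#'   integer vector gene -> planted module label with 0 = background;
#'   `shifts`, the per-module case shift).
#' @export
simulate_expression <- function(config) {
  assert_that(inherits(config, "expr_sim_config"),
              "config must come from expr_sim_config()")
  set.seed(config$seed)
  n_s <- config$n_control + config$n_case
  sample_ids <- c(sprintf("LM_%d", seq_len(config$n_control)),
                  sprintf("TG_%d", seq_len(config$n_case)))
  group <- rep(c("control", "case"), c(config$n_control, config$n_case))
  case <- as.numeric(group == "case")

  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  modules <- integer(config$n_genes)
  idx <- 1L
  for (m in seq_along(config$module_sizes)) {
    modules[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }
  names(modules) <- gene_ids

  expr <- matrix(NA_real_, config$n_genes, n_s,
                 dimnames = list(gene_ids, sample_ids))
  for (m in seq_along(config$module_sizes)) {
    e_m <- stats::rnorm(n_s) + config$case_shift_per_module[m] * case
    genes_m <- which(modules == m)
    rho <- stats::runif(length(genes_m),
                        config$module_gene_loading_range[1],
                        config$module_gene_loading_range[2])
    noise <- matrix(stats::rnorm(length(genes_m) * n_s), length(genes_m), n_s)
    expr[genes_m, ] <- rho %o% e_m + sqrt(1 - rho^2) * noise
  }
  bg <- which(modules == 0L)
  if (length(bg) > 0)
    expr[bg, ] <- matrix(stats::rnorm(length(bg) * n_s, sd = config$background_sd),
                         length(bg), n_s)
  expr <- expr + config$intensity_offset

  traits <- data.frame(sample_id = sample_ids, group = group,
                       stringsAsFactors = FALSE)
  truth <- list(modules = modules, shifts = config$case_shift_per_module)
  list(expr = expr, traits = traits, truth = truth)
}

#' Configuration for the marker-cohort simulator
#'
#' Emulates a two-group human cohort of qPCR relative-expression values.
#' Controls are log-normal with geometric mean 1 and log-scale SD `log_cv`;
#' marker dependence follows the Gaussian copula implied by
#' `marker_correlation`. A random `subset_fraction` of cases (independent
#' Bernoulli draws) has the `subset_markers` multiplied by
#' `subset_multiplier`, planting the low-expressing patient subset the panel
#' classifier is meant to detect.
#'
#' @param n_control,n_case group sizes (defaults 45 controls / 54 patients).
#' @param markers marker names.
#' @param subset_fraction expected fraction of cases in the planted subset.
#' @param subset_markers markers reduced in the subset.
#' @param subset_multiplier multiplicative reduction (in (0,1)).
#' @param log_cv SD of natural-log expression in all subjects.
#' @param marker_correlation PSD correlation matrix (diag 1) of the latent
#'   Gaussian; identity by default.
#' @param seed integer seed.
#' @return object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_control = 45L,
                              n_case = 54L,
                              markers = c("RGS1", "CCL4"),
                              subset_fraction = 0.27,
                              subset_markers = c("RGS1", "CCL4"),
                              subset_multiplier = 0.3,
                              log_cv = 0.2,
                              marker_correlation = diag(length(markers)),
                              seed = 1L) {
  assert_that(is_count(n_control) && is_count(n_case) &&
                n_control >= 1 && n_case >= 1, "group sizes must be positive counts")
  assert_that(subset_fraction >= 0 && subset_fraction <= 1,
              "subset_fraction must lie in [0,1]")
  assert_that(all(subset_markers %in% markers),
              "subset_markers must be a subset of markers")
  assert_that(subset_multiplier > 0 && subset_multiplier < 1,
              "subset_multiplier must lie in (0,1)")
  assert_that(log_cv > 0, "log_cv must be positive")
  R <- as.matrix(marker_correlation)
  assert_that(nrow(R) == length(markers) && ncol(R) == length(markers),
              "marker_correlation must be %d x %d", length(markers), length(markers))
  assert_that(all(abs(diag(R) - 1) < 1e-12), "correlation diagonal must be 1")
  assert_that(max(abs(R - t(R))) < 1e-12, "correlation matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8, "marker_correlation is not positive semidefinite")
  structure(list(n_control = as.integer(n_control), n_case = as.integer(n_case),
                 markers = markers, subset_fraction = subset_fraction,
                 subset_markers = subset_markers,
                 subset_multiplier = subset_multiplier,
                 log_cv = log_cv, marker_correlation = R,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a two-group cohort of marker relative-expression values
#'
#' @param config a [cohort_sim_config()].
#' @return list with `expr` (data.frame: sample_id then one column per
#'   marker), `labels` (data.frame: sample_id, group) and `subset_truth`
#'   (named logical vector over case samples: planted subset membership).
#' @export
simulate_qpcr_cohort <- function(config) {
  assert_that(inherits(config, "cohort_sim_config"),
              "config must come from cohort_sim_config()")
  set.seed(config$seed)
  n <- config$n_control + config$n_case
  p <- length(config$markers)
  sample_ids <- c(sprintf("CTRL_%02d", seq_len(config$n_control)),
                  sprintf("SCZ_%02d", seq_len(config$n_case)))
  group <- rep(c("control", "case"), c(config$n_control, config$n_case))

  # Gaussian copula with log-normal margins, geometric mean 1
  L <- chol(config$marker_correlation + diag(1e-10, p))
  z <- matrix(stats::rnorm(n * p), n, p) %*% L
  vals <- exp(config$log_cv * z)
  colnames(vals) <- config$markers

  in_subset <- stats::runif(config$n_case) < config$subset_fraction
  names(in_subset) <- sample_ids[group == "case"]
  case_rows <- which(group == "case")[in_subset]
  vals[case_rows, config$subset_markers] <-
    vals[case_rows, config$subset_markers] * config$subset_multiplier

  expr <- data.frame(sample_id = sample_ids, vals,
                     stringsAsFactors = FALSE, check.names = FALSE)
  labels <- data.frame(sample_id = sample_ids, group = group,
                       stringsAsFactors = FALSE)
  list(expr = expr, labels = labels, subset_truth = in_subset)
}

#' Configuration for the clinical-covariate simulator
#'
#' Two groups of subjects (e.g. marker-negative vs marker-positive patients)
#' with per-group normal continuous covariates and multinomial categorical
#' covariates. Defaults reproduce the covariate structure of the clinical
#' comparison this package accompanies: 37 vs 13 subjects with age, illness
#' duration, hospitalizations, PANSS scales, sex, clozapine use, language
#' and handedness.
#'
#' @param group_sizes integer vector of length 2 (negative, positive).
#' @param continuous named list; each element `list(mean = c(g1, g2), sd = c(g1, g2))`.
#' @param categorical named list; each element `list(levels = chr, prob = 2 x k matrix)`
#'   with rows summing to 1.
#' @return object of class `clinical_sim_config`.
#' @export
clinical_sim_config <- function(group_sizes = c(37L, 13L),
                                continuous = NULL,
                                categorical = NULL) {
  if (is.null(continuous)) {
    continuous <- list(
      age              = list(mean = c(32.24, 40.00), sd = c(11.13, 11.19)),
      duration_illness = list(mean = c(8.55, 9.54),  sd = c(9.04, 8.33)),
      hospitalizations = list(mean = c(4.03, 3.15),  sd = c(3.33, 1.57)),
      panss_total      = list(mean = c(61.67, 54.92), sd = c(17.50, 12.44)),
      panss_positive   = list(mean = c(14.03, 11.54), sd = c(5.59, 3.57)),
      panss_negative   = list(mean = c(16.75, 16.69), sd = c(5.12, 6.58)),
      panss_general    = list(mean = c(30.89, 26.69), sd = c(9.31, 4.11)))
  }
  if (is.null(categorical)) {
    categorical <- list(
      sex        = list(levels = c("male", "female"),
                        prob = rbind(c(29, 9) / 38, c(8, 2) / 10)),
      clozapine  = list(levels = c("yes", "no"),
                        prob = rbind(c(5, 32) / 37, c(8, 5) / 13)),
      language   = list(levels = c("german", "foreign"),
                        prob = rbind(c(30, 7) / 37, c(13, 0) / 13)),
      handedness = list(levels = c("right", "left", "both"),
                        prob = rbind(c(33, 4, 0) / 37, c(11, 1, 1) / 13)))
  }
  assert_that(length(group_sizes) == 2 && all(group_sizes > 0),
              "two positive group sizes required")
  for (nm in names(continuous)) {
    cv <- continuous[[nm]]
    assert_that(length(cv$mean) == 2 && length(cv$sd) == 2 && all(cv$sd >= 0),
                "continuous covariate '%s' needs per-group mean and sd >= 0", nm)
  }
  for (nm in names(categorical)) {
    cv <- categorical[[nm]]
    assert_that(is.matrix(cv$prob) && nrow(cv$prob) == 2 &&
                  ncol(cv$prob) == length(cv$levels),
                "categorical covariate '%s' needs a 2 x levels prob matrix", nm)
    assert_that(all(abs(rowSums(cv$prob) - 1) < 1e-8) && all(cv$prob >= 0),
                "probabilities for '%s' must be non-negative and sum to 1", nm)
  }
  structure(list(group_sizes = as.integer(group_sizes),
                 continuous = continuous, categorical = categorical),
            class = "clinical_sim_config")
}

#' Simulate a clinical covariate table
#'
#' @param config a [clinical_sim_config()].
#' @param seed integer seed.
#' @return data.frame with subject_id, group
#'   (`marker_negative`/`marker_positive`) and one column per covariate.
#' @export
simulate_clinical_table <- function(config = clinical_sim_config(), seed = 1L) {
  assert_that(inherits(config, "clinical_sim_config"),
              "config must come from clinical_sim_config()")
  set.seed(seed)
  n <- config$group_sizes
  group <- rep(c("marker_negative", "marker_positive"), n)
  out <- data.frame(subject_id = sprintf("S%03d", seq_len(sum(n))),
                    group = group, stringsAsFactors = FALSE)
  gi <- rep(1:2, n)
  for (nm in names(config$continuous)) {
    cv <- config$continuous[[nm]]
    out[[nm]] <- stats::rnorm(sum(n), mean = cv$mean[gi], sd = cv$sd[gi])
  }
  for (nm in names(config$categorical)) {
    cv <- config$categorical[[nm]]
    out[[nm]] <- vapply(gi, function(g)
      sample(cv$levels, 1L, prob = cv$prob[g, ]), character(1))
  }
  out
}
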