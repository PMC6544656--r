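# End-to-end pipeline orchestration: preprocess -> differential expression
# -> coexpression network -> hubs/centrality on the expression arm, and
# cohort simulation/classification -> clinical statistics on the
# translation arm. Stages communicate via files in the run directory so
# each stage's output can be audited and re-entered; a manifest records
# parameters, seed, versions, row counts and file hashes.

#' Write / read a genes x samples TSV matrix
#'
#' Tab-separated, header row of sample IDs, first column `gene_id`,
#' `.` decimal.
#'
#' @param m matrix to write.
#' @param path file path.
#' @return `read_expression_tsv` returns the matrix; `write_expression_tsv`
#'   its path, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Pipeline configuration
#'
#' Collects every stage parameter with the package defaults: 20th-percentile
#' background filter; p = 0.01 / FC >= 1.2 differential-expression cut;
#' beta = 6 unsigned network with TOM clustering (cut height 0.99, minimum
#' module size 20, merge height 0.25); hub thresholds |MM| > 0.8,
#' |GS| > 0.5, kIM_norm > 0.5; module-graph edge cutoff 0.2; 50%%-of-control
#' panel threshold at alpha = 0.05. `seed` drives all simulated inputs.
#'
#' @param seed integer master seed.
#' @param expr_config an [expr_sim_config()] (simulated discovery arm).
#' @param cohort_config a [cohort_sim_config()] (simulated translation arm).
#' @param clinical_config a [clinical_sim_config()].
#' @param lower_pct,p_threshold,fc_cutoff,beta,min_module_size,cut_height,merge_cut_height,mm_min,gs_min,kim_min,edge_cutoff,fraction,alpha stage parameters (see the stage functions).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            expr_config = expr_sim_config(seed = seed),
                            cohort_config = cohort_sim_config(seed = seed + 1L),
                            clinical_config = clinical_sim_config(),
                            lower_pct = 20, p_threshold = 0.01, fc_cutoff = 1.2,
                            beta = 6, min_module_size = 20, cut_height = 0.99,
                            merge_cut_height = 0.25,
                            mm_min = 0.8, gs_min = 0.5, kim_min = 0.5,
                            edge_cutoff = 0.2, fraction = 0.5, alpha = 0.05) {
  structure(list(seed = as.integer(seed), expr_config = expr_config,
                 cohort_config = cohort_config,
                 clinical_config = clinical_config,
                 lower_pct = lower_pct, p_threshold = p_threshold,
                 fc_cutoff = fc_cutoff, beta = beta,
                 min_module_size = min_module_size, cut_height = cut_height,
                 merge_cut_height = merge_cut_height, mm_min = mm_min,
                 gs_min = gs_min, kim_min = kim_min,
                 edge_cutoff = edge_cutoff, fraction = fraction, alpha = alpha),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full reverse-translation pipeline
#'
#' Expression arm: simulate (or accept) a discovery matrix, background
#' filter, quantile normalization, median baseline, moderated-t
#' differential expression, coexpression network with module detection and
#' module-trait significance, then hub selection and stress centrality on
#' the top trait-associated module. Translation arm: simulate (or accept) a
#' marker cohort, threshold-panel classification, the differential Spearman
#' correlation matrix, and the clinical group-comparison report. All stage
#' outputs land in `out_dir` together with `manifest.json` (parameters,
#' seed, package version, per-stage row counts, MD5 per file). Reruns with
#' the same config produce byte-identical tabular outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @param expr,traits optional pre-made expression matrix and traits
#'   (skips the expression simulation).
#' @param cohort optional pre-made cohort list (`expr`, `labels`) as from
#'   [simulate_qpcr_cohort()].
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         expr = NULL, traits = NULL, cohort = NULL) {
  assert_that(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  counts <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- expression arm -------------------------------------------------
  sim <- NULL
  if (is.null(expr)) {
    sim <- stage("simulate_expression", simulate_expression(config$expr_config))
    expr <- sim$expr; traits <- sim$traits
    files <- c(files, write_tsv(data.frame(gene_id = names(sim$truth$modules),
                                           module = sim$truth$modules),
                                file.path(out_dir, "truth.tsv")))
  }
  files <- c(files, write_expression_tsv(expr, file.path(out_dir, "raw.tsv")),
             write_tsv(traits, file.path(out_dir, "samples.tsv")))

  norm <- stage("preprocess", {
    keep <- background_filter(expr, traits, lower_pct = config$lower_pct)
    m <- quantile_normalize(expr[keep, , drop = FALSE])
    m <- baseline_transform(m)
    suppressMessages(drop_zero_variance(m))
  })
  counts$genes_after_filter <- nrow(norm)
  files <- c(files, write_expression_tsv(norm, file.path(out_dir, "norm.tsv")))

  de <- stage("diffexpr", {
    n1 <- sum(traits$group == "case"); n2 <- sum(traits$group == "control")
    res0 <- moderated_t(norm, traits, list(d0 = 0, s0_sq = 1))
    prior <- estimate_variance_prior(res0$s_sq, n1 + n2 - 2)
    res <- moderated_t(norm, traits, prior)
    de_table(res, config$p_threshold, config$fc_cutoff)
  })
  counts$de_genes <- nrow(de)
  files <- c(files, write_tsv(de, file.path(out_dir, "de.tsv")))

  net <- stage("coexpression", {
    cc <- correlation_matrix(norm)
    a <- adjacency(cc, config$beta)
    tom <- topological_overlap(a)
    det <- detect_modules(tom, config$min_module_size, config$cut_height,
                          config$merge_cut_height, norm)
    mt <- if (!is.null(det$eigengenes))
      module_trait_table(det$eigengenes, traits, config$alpha) else NULL
    list(adjacency = a, modules = det$modules, eigengenes = det$eigengenes,
         module_trait = mt)
  })
  counts$modules <- if (is.null(net$module_trait)) 0L else net$module_trait$n_modules
  counts$significant_modules <-
    if (is.null(net$module_trait)) 0L else net$module_trait$n_significant
  files <- c(files, write_tsv(data.frame(gene_id = names(net$modules),
                                         module = net$modules),
                              file.path(out_dir, "modules.tsv")))
  if (!is.null(net$eigengenes))
    files <- c(files,
               write_tsv(data.frame(sample_id = rownames(net$eigengenes),
                                    net$eigengenes, check.names = FALSE),
                         file.path(out_dir, "eigengenes.tsv")))
  if (!is.null(net$module_trait))
    files <- c(files, write_tsv(net$module_trait$table,
                                file.path(out_dir, "module_trait.tsv")))

  hubs <- NULL
  top <- if (is.null(net$module_trait)) NA else net$module_trait$top_module
  if (!is.na(top)) {
    hubs <- stage("hubs_centrality", {
      st <- gene_module_statistics(norm, net$modules, net$eigengenes, traits,
                                   net$adjacency)
      sel <- select_hub_genes(st, config$mm_min, config$gs_min, config$kim_min)
      top_lab <- as.integer(sub("^ME", "", top))
      genes <- names(net$modules)[net$modules == top_lab]
      g <- threshold_graph(net$adjacency, genes, config$edge_cutoff)
      ce <- stress_centrality(g)
      export_network(g, ce, st, file.path(out_dir, "network.sif"),
                     file.path(out_dir, "network.graphml"))
      list(stats = st, hubs = sel, graph = g, centrality = ce)
    })
    counts$hub_genes <- nrow(hubs$hubs$hubs)
    files <- c(files,
               write_tsv(hubs$hubs$hubs, file.path(out_dir, "hubs.tsv")),
               write_tsv(hubs$centrality, file.path(out_dir, "centrality.tsv")),
               file.path(out_dir, "network.sif"),
               file.path(out_dir, "network.graphml"))
  }

  # --- translation arm ------------------------------------------------
  if (is.null(cohort))
    cohort <- stage("simulate_cohort", simulate_qpcr_cohort(config$cohort_config))
  files <- c(files,
             write_tsv(cohort$expr, file.path(out_dir, "cohort_expr.tsv")),
             write_tsv(cohort$labels, file.path(out_dir, "cohort_labels.tsv")))

  panel <- stage("biomarker_panel", {
    markers <- setdiff(names(cohort$expr), c("sample_id", "group"))
    pr <- classify_samples(cohort$expr, cohort$labels, markers, config$fraction)
    dc <- if (length(markers) >= 2)
      differential_correlation_matrix(cohort$expr, cohort$labels, markers,
                                      config$alpha) else NULL
    list(panel = pr, diffcor = dc)
  })
  counts$panel_samples <- nrow(panel$panel$calls)
  panel_json <- list(fraction = panel$panel$fraction,
                     thresholds = as.list(panel$panel$thresholds),
                     performance = panel$panel$performance,
                     calls = panel$panel$calls)
  jsonlite::write_json(panel_json, file.path(out_dir, "panel.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, file.path(out_dir, "panel.json"))
  if (!is.null(panel$diffcor))
    files <- c(files, write_tsv(panel$diffcor, file.path(out_dir, "diffcor.tsv")))

  clin_report <- stage("clinical_stats", {
    clin <- simulate_clinical_table(config$clinical_config, seed = config$seed + 2L)
    tests <- c(age = "anova", duration_illness = "anova",
               hospitalizations = "welch",
               panss_total = "anova", panss_positive = "anova",
               panss_negative = "anova", panss_general = "welch",
               sex = "chisq", clozapine = "chisq", language = "chisq",
               handedness = "chisq")
    group_comparison_table(clin, tests)
  })
  counts$clinical_rows <- nrow(clin_report)
  files <- c(files, write_tsv(clin_report, file.path(out_dir, "clinical_report.tsv")))

  manifest <- list(
    package = "revtranslate",
    version = as.character(utils::packageVersion("revtranslate")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("expr_config", "cohort_config",
                                  "clinical_config"))],
    stages = counts,
    files = lapply(stats::setNames(nm = basename(unique(files))), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(norm = norm, de = de, network = net, hubs = hubs,
                 cohort = cohort, panel = panel, clinical = clin_report,
                 truth = if (!is.null(sim)) sim$truth else NULL,
                 manifest = manifest))
}
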