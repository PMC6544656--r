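# revtranslate

Reverse-translation biomarker analysis for case-control expression
studies: discover a trait-associated coexpression module in a small
animal-model experiment, carry its hub genes into a human cohort as a
qPCR marker panel, and quantify how well the panel separates patients
from controls.

The package is aimed at analysts working with small two-group expression
designs (microarray- or qPCR-scale) who need the full chain —
preprocessing, moderated differential expression, weighted coexpression
network, hub/centrality analysis, ΔΔCt quantification, panel
sensitivity/specificity, and clinical group statistics — as tested,
scriptable R functions rather than a point-and-click workflow.

## What it computes

**Expression arm.** Starting from a gene x sample log2-intensity matrix:
a background-percentile filter (expressed at or above the 20th percentile
of its own array in all replicates of at least one group), quantile
normalization, and per-gene median baseline. Differential expression uses
an empirical-Bayes moderated t: gene variances are shrunk toward a prior
(s0², d0) estimated by log-variance moment matching, giving
t̃ = (x̄_case − x̄_control) / (s̃ √(1/n₁ + 1/n₂)) with
s̃² = (d0·s0² + d_g·s_g²)/(d0 + d_g) on d0 + d_g df. The unsigned
coexpression network is a_mn = |cor(m,n)|^β (β = 6 by default, with
scale-free-topology selection available), smoothed into a topological
overlap matrix; modules come from average-linkage clustering on 1 − TOM
with static cut and eigengene merging, and the module whose eigengene
correlates most significantly with the trait is carried forward. Hub
genes satisfy |MM| > 0.8, |GS| > 0.5, kIM_norm > 0.5; the module graph
(adjacency > 0.2) is ranked by Shimbel stress centrality (shortest-path
counts through each node) and exports to SIF/GraphML for Cytoscape.

**Translation arm.** qPCR relative expression by ΔΔCt against a
housekeeping gene and a per-plate calibrator (expression = 2^−ΔΔCt); a
control-anchored classifier that flags a sample when a marker falls below
50% of the control mean, combined across markers by AND; sensitivity and
specificity in percent; a case-vs-control differential Spearman
correlation matrix (relations kept / lost / gained); and the clinical
comparison statistics (ANOVA from raw data or printed summaries, Welch
ANOVA, Pearson chi-square, Mann-Whitney U, Kendall tau-b, ANCOVA).

Seeded generators (`simulate_expression()`, `simulate_qpcr_cohort()`,
`simulate_clinical_table()`) produce synthetic inputs with planted
structure, so every stage — and the pipeline end to end — runs and is
tested without any external download.

## Worked example

```r
library(revtranslate)

res <- run_pipeline(pipeline_config(seed = 3), out_dir = "run")

head(res$de[, c("gene", "fold_change", "direction", "t", "p")], 3)
#>        gene fold_change direction     t        p
#> 1 gene_1825        4.00      down -3.68 0.000237
#> 2 gene_0989        3.84        up  3.57 0.000355
#> 3 gene_1924        3.54      down -3.36 0.000793

mt <- res$network$module_trait
mt$table[mt$table$module == mt$top_module, ]
#>   module      r       p significant
#> 3    ME3 -0.787 0.00237        TRUE

res$panel$panel$performance
#>        marker TP FP TN FN sensitivity specificity
#> 1        RGS1 13  0 45 41        24.1         100
#> 2        CCL4 13  0 45 41        24.1         100
#> 3 combination 13  0 45 41        24.1         100
```

The run simulates the default discovery design (2,000 genes, 7 control +
5 case samples, a 50-gene module shifted down 1.5 SD in cases), keeps 969
genes past the background filter, finds 31 screening hits at p ≤ 0.01
and FC ≥ 1.2, detects 17 modules of which 3 are trait-significant, and
selects the planted down-shifted module as top (eigengene-trait
r = −0.787, p = 0.0024). On the simulated 45/54 human cohort with a
planted 27% low-expressing patient subset, the RGS1+CCL4 AND-panel
detects 13 of 54 patients (24.1% sensitivity) with no false positives
(100% specificity) in this seed. All stage outputs land in `run/`
(TSV/JSON) together with a manifest recording parameters, seed, row
counts and file hashes; reruns with the same seed are byte-identical.

Clinical statistics work directly from printed summary rows as well:

```r
anova_from_summary(32.24, 11.13, 37, 40, 11.19, 13)
#> F = 4.664, df = 1, 48, p = 0.03583
```

A thin command-line wrapper is installed at
`inst/scripts/revtranslate.R` (`all` and `simulate` subcommands).

## Vignette

`vignettes/reverse-translation-methods.Rmd` documents the models, the
estimators, every tunable parameter with its default and rationale, what
the synthetic generators do and do not emulate, and the attainable
recovery rates at the discovery sample size.
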