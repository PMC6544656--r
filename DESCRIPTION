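Package: revtranslate
Title: Reverse-Translation Biomarker Analysis for Case-Control Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for reverse-translation biomarker discovery from bulk
    expression profiles: background-percentile filtering, quantile
    normalization and median baseline transformation of gene-level
    log2-intensity matrices; empirical-Bayes moderated t-tests with fold-change
    ranking; an unsigned weighted gene coexpression network (soft-thresholded
    adjacency, topological overlap, average-linkage module detection with
    eigengene merging, module-trait significance); hub-gene selection and
    stress-centrality ranking on thresholded module graphs; qPCR delta-delta-Ct
    relative quantification; a control-anchored two-marker panel classifier
    with sensitivity and specificity; case-control differential Spearman
    correlation matrices; and the accompanying clinical group-comparison
    statistics. Includes seeded synthetic-data generators that emulate the
    statistical structure of the discovery (rat) and validation (human cohort)
    designs so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
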