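---
title: "Methods: reverse-translation biomarker analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reverse-translation biomarker analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revtranslate)
```

## Overview

`revtranslate` implements a reverse-translation workflow for biomarker
discovery: a small case-control expression experiment (typically an animal
model) is mined for a coherent, trait-associated coexpression module; hub
genes of that module are carried into a human cohort as a qPCR marker
panel; and the panel's operating characteristics and the accompanying
clinical statistics are computed. Every stage runs on plain matrices and
data frames, and seeded generators supply synthetic inputs with the
statistical structure each stage assumes, so the whole chain is testable
without external data.

## Preprocessing

The expression arm starts from a gene-level log2-intensity matrix.

* **Background filter.** A gene is retained when its signal sits at or
  above the 20th percentile of its own array's value distribution in *all*
  replicates of at least one group. The percentile estimator is linear
  interpolation between order statistics (R's type 7); the filter is
  applied to the raw, pre-normalization matrix. One group suffices on
  purpose: a transcript silenced in cases but expressed in every control is
  exactly the kind of signal the comparison is after.
* **Quantile normalization** forces all samples onto the distribution of
  row-rank means (ties get the average of the tied reference values). It is
  idempotent and leaves within-sample ranks untouched.
* **Baseline transformation** subtracts each gene's across-sample median,
  so downstream fold changes read directly as deviations from the cohort
  median.

Genes with zero variance after preprocessing are dropped (their
correlations are undefined) with a logged message.

## Moderated differential expression

With as few as 7 + 5 samples, gene-wise variance estimates are unstable,
so the two-group comparison uses an empirical-Bayes moderated t. Gene
variances are modelled as scaled inverse-chi-square draws around a prior
variance $s_0^2$ with prior degrees of freedom $d_0$; the moderated
statistic replaces the pooled variance $s_g^2$ (residual df $d_g$) by

$$\tilde s^2_g = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and is referred to a Student-t with $d_0 + d_g$ df. The prior is estimated
by moment matching on $\log s_g^2$: the excess dispersion of
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$ beyond
$\psi'(d_g/2)$ estimates $\psi'(d_0/2)$, inverted by Newton iteration;
zero excess dispersion yields $d_0 = \infty$ with $s_0^2$ the mean sample
variance. `d0 = 0` recovers the ordinary pooled t exactly, and
$d_0 \to \infty$ pins every gene at $s_0^2$ — both limits are unit-tested,
and the estimator is cross-checked against an independent
F-distribution fit in the test suite.

The screening table keeps genes with $p \le 0.01$ and fold change at or
above a cutoff (1.2 by default in the pipeline), sorted by fold change.
Deliberately, *no* multiple-testing correction is applied: the threshold
is a per-gene screen feeding a network stage that aggregates evidence
across genes, not a hypothesis-level claim.

## Coexpression network

The network is unsigned and weighted: $a_{mn} = |\mathrm{cor}(m,n)|^\beta$
with $\beta = 6$ as the operating default. `pick_soft_threshold()`
implements scale-free-topology selection (connectivity histogram on a
log-log grid, fit index signed negative for positive slopes, smallest
candidate reaching $R^2 \ge 0.8$) for users who want to re-derive
$\beta$ on their data. The topological overlap

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad
\ell_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj}$$

smooths adjacency by shared neighbourhood; $1 - \mathrm{TOM}$ is the
clustering distance. Modules come from average-linkage hierarchical
clustering with a *static* cut (default height 0.99) and a minimum module
size (default 20; the tests use 10 on small fixtures), followed by
iterative merging of modules whose eigengene dissimilarity
$1 - \mathrm{cor}(ME_a, ME_b)$ falls below 0.25, closest pair first. A
static cut is the simplest faithful reading of "cluster, then merge
similar modules"; dynamic tree cutting is deliberately out of scope.

A module eigengene is the unit-norm first principal component of the
module's standardized expression, sign-oriented so its mean correlation
with the module genes is non-negative; because genes are centred, the
eigengene is exactly zero-mean across samples. Module-trait association
is the Pearson correlation between eigengene and the 0/1 group indicator,
with the Student-t p-value $t = r\sqrt{n-2}/\sqrt{1-r^2}$; the selected
"top" module is the significant module of largest $|r|$.

## Hubs and stress centrality

Per gene the package reports module membership (MM, correlation with the
module eigengene), gene-trait significance (GS), and intramodule
connectivity kIM (sum of adjacency to module partners, normalized by the
module maximum). Hubs satisfy $|MM| > 0.8$, $|GS| > 0.5$ and
$kIM_{norm} > 0.5$, all strict, and are split by the sign of GS into
down-in-case and up-in-case subsets, ranked by the mean of $|MM|$ and
$|GS|$ then by $kIM_{norm}$. The ranking key is one reasonable reading of
"mean correlation"; it is a documented package decision, not an external
standard.

The module graph connects genes whose adjacency strictly exceeds 0.2;
edges are unweighted for path computations (weights are kept for export
only). Stress centrality counts, for each node $v$, the shortest paths
between unordered pairs of other nodes that pass through $v$; it is
computed from all-pairs BFS path counts
($\sigma_{st}(v) = \sigma_{sv}\sigma_{vt}$ when
$d(s,t) = d(s,v) + d(v,t)$) and validated against a brute-force
enumeration of every shortest path on random graphs of up to 8 nodes.
Counting unordered pairs once is a package convention, applied
consistently in both the implementation and the oracle. Networks export
to SIF and GraphML (with stress, degree, MM, GS and adjacency
attributes) for Cytoscape.

## qPCR quantification and the marker panel

Relative expression is plain $\Delta\Delta C_t$ with amplification
efficiency fixed at 2: normalize the target to a housekeeping gene within
each sample, anchor to a calibrator sample run on every plate, report
$2^{-\Delta\Delta C_t}$ so the calibrator is 1 and plate-wide shifts
cancel exactly. Technical replicates are averaged on the Ct scale before
any differencing. A sample with target Ct strictly above 29 cycles is
called non-expressing.

The panel classifier is control-anchored: a marker "detects" a sample
when its relative expression falls strictly below half the arithmetic
mean of the control samples, and a marker combination detects a sample
when *all* member markers do (AND rule — the only rule whose combined
sensitivity cannot exceed any single marker while its specificity cannot
fall below any, which is the printed pattern the rule must reproduce).
Sensitivity and specificity are reported in percent with "positive"
meaning detected. The differential correlation matrix computes Spearman's
rho (midranks, Student-t p) per marker pair within each group and labels
pairs `both`, `control_only` (lost in cases), `case_only` (gained) or
`neither` at $\alpha = 0.05$ per group.

## Clinical statistics

Group comparisons deliberately mirror a clinical reporting table:
one-way ANOVA (computable from raw data or from printed means/SDs/ns,
identical by construction), Welch's ANOVA with Satterthwaite df when
variance homogeneity is doubtful, Pearson chi-square without continuity
correction for categorical covariates, Mann-Whitney U (exact for small
untied samples, tie-corrected normal otherwise), Kendall's tau-b, and
one-way ANCOVA with partial F tests. No multiplicity correction is
applied anywhere, matching the reporting convention of the accompanying
analysis. The choice of plain Pearson chi-square is validated by
recomputing published table rows from their printed counts to the printed
precision.

## Synthetic data: what it emulates, and what it does not

`simulate_expression()` emulates the discovery design: 7 control and 5
case samples, 2,000 genes on a microarray-like log2 scale (offset +8), two
planted 50-gene modules driven by latent factors with per-gene loadings
uniform in (0.7, 0.95), one module's factor shifted down by 1.5
within-group SD in cases, and independent Gaussian background. The case
shift acts on the latent factor, not per gene, so the eigengene-level
trait association is exactly the quantity the network stage tests.
`simulate_qpcr_cohort()` emulates the validation cohort: 45 controls and
54 patients, log-normal marker expression (geometric mean 1, log-SD 0.2)
under a Gaussian copula, and an independent-Bernoulli 27% patient subset
whose RGS1 and CCL4 are multiplied by 0.3. `simulate_clinical_table()`
draws per-group normal and multinomial covariates matching a published
demographic table's summary statistics.

Real data differ in ways the generators do not model: mean-variance
dependence and per-gene baseline heterogeneity, batch structure,
heavy-tailed noise, many modules of varying size, and marker assays with
missingness. Passing tests therefore demonstrate correctness of the
computations and recoverability of planted signal under the stated
design — not performance on any real cohort.

One interaction deserves a flag: because every simulated gene shares the
same baseline mean, the 20th-percentile background filter — benign on
real arrays, where it separates expressed from unexpressed transcripts
that sit orders of magnitude apart — removes roughly half of the
simulated genes near-arbitrarily, and hits the down-shifted module
hardest (its case-sample values sit low by construction). The full
pipeline therefore filters before networking, exactly as it would on
real data, while the recovery studies score the network stage on the
unfiltered simulated matrix, where the planted-module question is
well-posed.

### Attainable recovery at the discovery scale

A point worth stating explicitly, because it governs what the end-to-end
suite can show: with a latent shift of 1.5 SD and 7 + 5 samples, the
module-trait test is equivalent to a two-sample t on the eigengene with
noncentrality $1.5\sqrt{7\cdot 5/12} \approx 2.56$ on 10 df, whose
two-sided power at $\alpha = 0.05$ is about 0.64. Moreover, with 12
samples a null gene has roughly a 4% chance of $|r| > 0.6$ against any
latent factor, so each run detects a few dozen noise modules and, at
$\alpha = 0.05$, about one falsely trait-significant eigengene per run
that can out-rank the planted module. The measured significant-top
recovery rate under the default design is accordingly ~45%, and rises
toward 1 only as the planted shift grows (the strong-signal tests use a
3-SD shift). This mirrors the real analysis setting, where a minority of
modules reach significance and the top one is chosen by correlation
magnitude.

## Numerical choices and edge cases

* Percentiles: type-7 linear interpolation (inclusive endpoints).
* Zero-variance genes are errors in `correlation_matrix()` (named in the
  message) and are removed by the preprocessing helper beforehand.
* `|r| = 1` returns p = 0 exactly in `cor_pvalue_student()`.
* Threshold comparisons follow their definitions strictly: hub thresholds
  and the 0.2 edge cutoff are strict `>`, the panel detection rule is
  strict `<`, the 29-cycle expression call is inclusive `<=`.
* Ties in module-trait top selection break by lower p; hub ranking ties
  break by kIM.
* All generators take one integer seed and touch no global RNG state
  beyond `set.seed` at entry; identical configs give bit-identical
  outputs, and the pipeline writes byte-identical files on reruns.

## Problem sizes in the shipped suites

The unit suites run on fixtures of tens to hundreds of genes. The
recovery studies (test suite and `scripts/acceptance.R`) use the full
default design — 2,000 genes x 12 samples across 50 seeds for the
expression arm, and 99-subject cohorts across 50 seeds for the panel —
sizes at which the complete study runs in a few minutes on a single core
while keeping Monte-Carlo error on reported rates near one percentage
point.

## Known limitations

* Static tree cut only; no dynamic-hybrid module detection, no
  signed/signed-hybrid networks, no block-wise approximation for very
  large gene sets.
* Probe-level summarization (CEL/RMA) is upstream of this package: input
  is a gene-level matrix.
* The qPCR model assumes perfect doubling per cycle; no efficiency
  calibration from standard curves.
* The panel explores only threshold AND combinations; no ROC optimization
  of the threshold fraction.
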