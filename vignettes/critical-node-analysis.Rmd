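---
title: "Critical-node analysis of PPI networks: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical-node analysis of PPI networks: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critnet)
```

`critnet` implements a complete hub-gene / critical-node workflow: from a
two-group expression matrix to a filtered differential gene set, onto a
protein–protein interaction network, through centrality computation and
threshold-based node selection, to gene-set enrichment of the selected
genes. This vignette is the package's own account of the statistical
choices behind each stage — what is assumed, what was genuinely open, and
what the tests do and do not establish.

## Differential expression

Expression values are assumed to be log2-scale intensities. Samples are
median-centered (`median_center()`), the minimal normalization under which
box plots of small array studies become comparable; we deliberately do not
quantile-normalize, because with three samples per group quantile
normalization can erase real group differences.

Genes are ranked by Welch's unequal-variance t-test on the log2 values
(`rank_genes()`). The ranking statistic was open: empirical-Bayes
moderated statistics (limma-style) are more powerful at small n, but the
plain Welch test is the simplest defensible choice and makes the ranking
self-contained. Two degenerate-input conventions are fixed: if both group
variances are zero the statistic is undefined, and we define p = 1 when
the group means agree and p = 0 when they differ — preserving the obvious
calls without dividing by zero. Ties in p are broken by |log2 FC|
descending, then gene id, so ranks are a deterministic permutation.

Fold change is the ratio of geometric means, `2^(mean_B − mean_A)` of the
log2 data. The selection keeps the `top_n = 250` most significant genes
and then applies **strict** fold-change inequalities (FC < 0.5 or
FC > 2.0): a gene at exactly 2.0 is excluded, reading "less than 0.5 and
more than 2" literally.

### What the t-test can and cannot do at n = 3

With three samples per group the Welch statistic has 2–4 degrees of
freedom and its null distribution is conservative: in our null
simulations the fraction of genes with p < 0.05 is about 0.03, not 0.05.
The calibration test therefore runs at 20 samples per group, where the
Satterthwaite approximation is accurate and the empirical rate sits on the
nominal one; at n = 3 the suite asserts only conservativeness (the rate
does not exceed the nominal level). Recovery of planted signals is limited
by the same instability: a null gene that draws a tiny sample variance can
outrank a genuinely changed gene, so even an 8-fold planted effect is
recovered at roughly 80–90% in the top-50 list, not perfectly. The
acceptance script reports the realized recovery count rather than
asserting perfection.

## The interaction network

`build_graph()` produces a simple undirected graph: self-loops are
dropped, duplicate and reversed edges collapsed. Edge confidence scores
are ignored — the analysis is topological and unweighted throughout.
`main_component()` extracts the largest connected component (ties broken
toward the component containing the lexicographically smallest node id),
because closeness is undefined across disconnected parts.

### Centralities

`compute_centralities()` implements Brandes' algorithm for shortest-path
betweenness directly (BFS from every source with geodesic-count
accumulation and dependency back-propagation), normalized by
(N−1)(N−2)/2 so values lie in [0, 1]. Closeness is
(N−1)/Σ<sub>m</sub> d(n, m), the reciprocal of the mean shortest-path
length. Both conventions match Cytoscape's NetworkAnalyzer, the de facto
reference for this workflow; under them, closeness values around 0.6–0.7
on a dense component are typical. The implementation is verified two
independent ways: against a brute-force oracle that literally enumerates
all geodesics per node pair (guided only by a distance matrix), and
against igraph's C implementation — both to 1e-9 on random connected
graphs.

### Scale-free diagnostic

`fit_power_law()` regresses log(count) on log(degree) by ordinary least
squares; the exponent b is the slope, the prefactor a = exp(intercept),
and R² is the squared Pearson correlation **of the logged pairs**. Natural
logs are used internally; the base affects neither b nor R². Degree-0
nodes are excluded (log undefined), as are zero counts. Whether the y-axis
holds counts or relative frequencies changes only a, never b or R²; the
package fits counts. This classic log-log OLS is a diagnostic, not a
rigorous power-law estimator (no maximum-likelihood fit, no tail cutoff
selection) — it answers "is the degree distribution roughly a declining
power law", which is all the hub analysis needs.

## Node selection

Three rules, each with a genuinely open detail now fixed:

* **Hubs** (`select_hubs()`): degree ≥ mean + 2·SD. The SD is the sample
  SD (N−1 denominator) and the comparison is inclusive, so the degenerate
  all-equal-degrees case (SD = 0) admits every node rather than none.
* **Central nodes** (`select_top_fraction()`): exactly ⌈0.05·N⌉ nodes per
  metric — the ceiling guarantees a non-empty selection at any N. Ties are
  broken by degree, then node id, so runs are reproducible. On a 257-node
  component the top 5% is 13 nodes.
* **Critical nodes**: hubs ∩ central. "Central" could mean the union or
  the intersection of the betweenness-top and closeness-top lists; the
  package defaults to the **intersection** (the stricter reading, which
  matches a small critical panel emerging from a dense component) and
  offers `central_mode = "union"` as a config switch.

## Enrichment

`enrich()` uses the right-tailed hypergeometric test — `P(X ≥ k)` for
overlap k, term size K, query size n, universe U — computed via the
stable tail routines of `phyper`. The universe is all genes annotated to
at least one term in the supplied GMT; query genes outside it are dropped
with a warning. Multiplicity is controlled by Holm's step-down procedure
(the "Bonferroni step-down" familiar from ClueGO) across all terms with
non-zero overlap; rows with adjusted p below `alpha = 0.05` are reported,
with %G/T = 100·k/K rounded **half-up** to two decimals (so 7.317 prints
as 7.32, matching the conventional table style).

Term redundancy is summarized by Cohen's kappa between the binary
gene-membership vectors of each term pair, and terms are clustered as the
connected components of the graph with edges at κ ≥ 0.4. This
intentionally approximates the iterative group-merging of ClueGO with a
simpler, fully deterministic rule; the packaged 34-term fixture reproduces
the published structure under it (the HIF-1 signaling row separates, all
other terms form one cluster). When both membership vectors are constant
and equal, expected agreement is 1 and kappa is defined as 1.

### Calibration of a discrete test

Because the hypergeometric null is discrete, `P(p < α)` under the null is
*strictly below* α, by a margin set by the point mass at the critical
overlap — with realistic term sizes the realized rate at α = 0.05 is
0.02–0.04, and no implementation can make it 0.05. The calibration test
therefore compares the empirical null rate with the analytically exact
expectation `E[P(X ≥ k_crit)]` for the simulated designs (a tighter check
than any band around the nominal level) and separately asserts validity:
the exact rate never exceeds α.

## The synthetic-data model

`generate_expression()` draws per-gene baselines from N(8, 2) on the log2
scale and adds i.i.d. N(0, σ) noise per entry — the standard log-normal
microarray abstraction. The planted effect is added to group B only, so
with σ = 0 every planted gene's fold change is exactly `2^log2_effect`.
Defaults mirror a small two-arm array study: 3 samples per group,
σ = 0.5, 8-fold planted effects. The generator does **not** simulate
probe-level artifacts, batch effects, inter-gene correlation, or
intensity-dependent variance; passing tests show the pipeline recovers
planted signals under its own assumptions, not that it is robust to those
real-data features.

`generate_scale_free_network()` grows a Barabási–Albert graph from an
m-clique seed (guaranteeing connectivity) with degree-proportional
attachment of m edges per new node. Its degree distribution has a clearly
negative log-log slope for n ≥ 500, which is what the fit diagnostic
requires. Real PPI networks differ (their density is set by the database,
and edges are correlated with study bias); the generator provides the
topological *shape* the method assumes, nothing more.
`generate_annotations()` draws term members uniformly — a pure null model
used for calibration. `generate_study_bundle()` wires the three together
the way the study design assumes: network nodes are the fold-change-passing
top genes plus 100 "added" partner genes, with m = 3 edges per node — a
generic sparse choice, since the true density of a database-derived
network is not a property of the method.

All generators are pure functions of their arguments including the seed:
they use a private RNG stream and restore the caller's RNG state.

## Problem sizes in the test suite

The suite verifies centralities on 30 random connected graphs up to 40
nodes (and exhaustively against enumeration on smaller ones), power-law
recovery on a 2000-node preferential-attachment graph, hypergeometric
p-values against complete draw enumeration for all configurations with
universe ≤ 12, DEG calibration on 200 null matrices of 100 genes, and
enrichment calibration on 500 null annotation tables of 20 terms — sizes
chosen so each property is measured with useful precision while the whole
suite stays fast.

## Known limitations

* The Welch ranking is noticeably conservative and noisy at n = 3 per
  group; a moderated-variance statistic would rank better but is out of
  scope.
* The power-law fit is a diagnostic OLS, not an MLE with goodness-of-fit.
* Kappa clustering by connected components can chain loosely related
  terms through intermediates; ClueGO's iterative merging would split
  such chains.
* Published critical-gene panels depend on the interaction database
  version used to build the network; the package reproduces the *method*
  and its fixture-derived quantities, not database-dependent tables.
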