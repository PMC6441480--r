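# critnet

Identification of critical nodes — candidate biomarker genes — from
two-group expression profiles and a protein–protein interaction (PPI)
network.

Tumour-grade transitions (the motivating case is colon cancer grade II →
grade III) are often studied by comparing small groups of expression
profiles, projecting the differential genes onto a PPI network, and asking
which gene products occupy the network positions where perturbations matter
most. `critnet` packages that workflow end to end, with every statistic
implemented transparently and tested against independent oracles.

## The method

Given a log2 expression matrix with groups A and B and an undirected
interaction network:

1. **Normalization** — samples are median-centered; per-sample five-number
   summaries (box-plot statistics) diagnose comparability.
2. **DEG selection** — genes are ranked by Welch's unequal-variance t-test;
   the top *N* (default 250) are kept and filtered to fold change
   FC = 2^(mean_B − mean_A) with FC < 0.5 or FC > 2; optionally only
   characterized (annotated) genes are retained.
3. **Network topology** — the interaction edge list (TSV or SIF) becomes a
   simple undirected graph; the main connected component is extracted; for
   every node the package computes degree, Brandes shortest-path
   betweenness (normalized by (N−1)(N−2)/2), and closeness
   (N−1)/Σd(n,m). The degree distribution is fitted by
   count = a·k^b via least squares on log–log values; a clearly negative
   b with high R² is the scale-free diagnostic that justifies hub analysis.
4. **Node selection** — *hubs*: degree ≥ mean + 2·SD; *central nodes*: top
   5% by betweenness and by closeness (intersection by default);
   *critical nodes*: hubs ∩ central — the candidate biomarker panel.
5. **Enrichment** — the critical set is tested against GMT gene sets by the
   right-tailed hypergeometric test with Holm correction; per-term
   %G/T = 100·k/K is reported, and significant terms are clustered by
   Cohen's kappa on their gene-membership vectors (edge at κ ≥ 0.4,
   clusters = connected components).

A synthetic-data module generates all inputs with known ground truth:
two-group log-normal expression with planted fold changes, connected
preferential-attachment (Barabási–Albert) networks, and random GMT
annotations. A packaged plain-text fixture ships the published 34-term
enrichment table of the six-gene critical set
{MAPK3, AKT1, SRC, TP53, GAPDH, ALB} for the colon-cancer use case.

## Worked example

```r
library(critnet)

dir <- tempfile("demo_")
bundle <- generate_study_bundle(dir, seed = 42)   # writes all input files
cfg <- pipeline_config(expression   = bundle$paths$expression,
                       groups       = bundle$paths$groups,
                       edges        = bundle$paths$edges,
                       annotations  = bundle$paths$annotations,
                       characterized = bundle$paths$characterized,
                       output_dir   = file.path(dir, "out"), seed = 42)
report <- run_pipeline(cfg)
```

```
[critnet] expression: 1000 genes x 6 samples
[critnet] DEG filter: 250 top-ranked -> 69 passing fold change
[critnet] characterized: 69 -> 66
[critnet] network: 169 nodes, 501 edges; main component 169 nodes, 501 edges
[critnet] power law: a=207.140 b=-1.693 R^2=0.798
[critnet] 8 hubs, 8 central -> 7 critical
[critnet] enrichment: 0 significant terms in 0 cluster(s)
```

Reading the log: of 1000 simulated genes (50 carry a planted 8-fold
effect), 69 of the top-250 ranked genes pass the two-fold filter and 66 are
characterized; the 169-node network (66 differential genes plus 100 added
partners, 3 dropped) is scale-free (b = −1.69, R² = 0.80); 8 nodes exceed
the mean + 2 SD degree cutoff, 8 are in both top-5% centrality lists, and
their intersection gives 7 critical nodes. Annotations here are random, so
no term is enriched — the expected null result.

The packaged fixture reproduces the published per-gene term counts:

```r
fx <- table2_fixture()
membership_counts(fx$rows, fx$query)
#> MAPK3  AKT1   SRC  TP53 GAPDH   ALB
#>    34    32    22    17     1     0
```

A command-line wrapper with subcommands `simulate`, `run`, `enrich` and
`fixtures` is installed under `exec/critnet`.

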