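---
title: "Hierarchical marker gene selection: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical marker gene selection: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiermarkers)
```

## The problem

One-vs-rest differential expression is the workhorse for annotating
clustered scRNA-seq data: each cluster is tested against the pooled
remainder and the top up-regulated genes become its markers. When clusters
belong to closely related cell types (say, two CD4 T subtypes), this
produces overlapping marker lists that capture the shared lineage signature
but say little about what separates the subtypes. In a markers-by-clusters
heatmap ordered block-diagonally, this shows up as bright *off-diagonal*
blocks: cluster A's markers glowing in cluster B's cells.

`hiermarkers` turns that observation into an algorithm. It groups clusters
so that one-vs-rest markers become specific to each group, and then recurses
inside each group, producing a cluster hierarchy whose every split carries
its own marker genes.

## The heatmap block score

Given a partition of the base clusters into $G$ groups and a marker table
with gene set $M_i$ for group $i$, the implicit heatmap has row blocks $M_i$
and column blocks equal to each group's cells. Writing $\bar H(M_i, C)$ for
the mean heatmap value of genes $M_i$ over cell set $C$:

$$
V_\mathrm{diag} = \sum_{i=1}^{G} \bar H(M_i, \mathrm{cells}_i), \qquad
V_\mathrm{off} = \sum_{i=1}^{G} \max_{c \notin \mathrm{group}_i}
  \bar H(M_i, \mathrm{cells}_c), \qquad
s = \frac{V_\mathrm{diag} - k\, V_\mathrm{off}}{G},
$$

with $k = 5$ by default (`scoring_config(k =)`). Higher $s$ means stronger
diagonal signal and weaker worst-case off-diagonal signal per group. A group
with an empty marker list contributes zero to both sums.

Two representation choices matter enough to spell out:

* **What the heatmap contains.** The score reads the per-gene z-scored
  layer clamped to $[0, 2.5]$ (`scoring_config(floor = 0, clip = 2.5)`).
  The upper clamp is the usual display convention for scaled expression
  heatmaps. The lower clamp at zero encodes that a block of *below-average*
  expression is absent signal, not negative signal. This is not cosmetic:
  with a symmetric clamp, off-diagonal blocks of well-separated clusters
  average negative values, so the $-k V_\mathrm{off}$ term turns into a
  *reward* for merging anything with anything, the stopping rule never
  fires, and the hierarchy degenerates. With the floor at zero, an empty
  off-diagonal block costs nothing and a bright one costs $k$ times its
  mean, which is the economy the method is built on. Both knobs are
  exposed (`floor = -2.5` restores the symmetric clamp; `layer =
  "lognorm"` scores normalized log expression instead).

* **Resolution of the off-diagonal maximum.** The maximum
  $\max_{c \notin \mathrm{group}_i}$ ranges over *base clusters* outside
  group $i$, not over the other merged groups
  (`scoring_config(off_blocks = "cluster")`). Taken at merged-group
  resolution, an off-diagonal signal concentrated in one cluster gets
  diluted as soon as that cluster is absorbed into a bigger group, so a
  *wrong* merge can launder away a penalty it did nothing to fix; greedy
  agglomeration then systematically prefers cross-lineage merges. Keeping
  the maximum at base-cluster resolution makes a concentrated off-diagonal
  block equally visible at every grouping level. The group-resolution
  variant remains available (`off_blocks = "group"`).

## Agglomeration and the divisive hierarchy

At each level the algorithm starts from every base cluster as its own group
and repeatedly evaluates all $\binom{G}{2}$ candidate merges. Each candidate
re-runs the one-vs-rest marker finder on the merged grouping (markers are
never carried over; a memo cache keyed on the exact partition avoids
redundant recomputation inside the pair loop) and re-scores the heatmap.
The best candidate is accepted only if it beats the current grouping's score
by more than a tie tolerance of 1e-9; ties among candidates go to the
smallest (i, j) index pair, making runs deterministic. Agglomeration stops
when no merge improves the score or when two groups remain (the score and
the one-vs-rest subroutine are undefined for a single group).

The final grouping defines one split of the divisive hierarchy: each group
becomes a child node, and the procedure recurses inside every child with at
least two member clusters, restricting the data to that child's cells, until
all leaves are single clusters. When the very first agglomeration accepts no
merge, the hierarchy collapses to a depth-1 tree whose split markers are
identical, gene for gene, to the flat one-vs-rest run — well-separated
datasets lose nothing by going through this machinery.

The scaled layer is computed once globally and reused when the recursion
restricts to a node's cells; expression is not re-standardized per node.
This keeps block means comparable across levels of the tree and avoids
making deep splits look artificially strong. The marker finder, by
contrast, always tests within the node's scope only, which is what gives
within-lineage splits their subtype-specific markers.

## Marker finding

Markers are found per group by a two-sided Wilcoxon rank-sum test of
normalized log expression, group versus all other cells in scope, vectorized
across genes with midrank tie handling, tie-corrected variance and
continuity correction. A separate exact mode computes the p-value from the
exact permutation distribution of the rank sum (a counting DP over the
midrank multiset, valid with ties) for pooled sizes up to 12; it exists for
verification and small-sample use, while the marker finder itself uses the
normal approximation appropriate to its sample sizes.

Genes are filtered to up-regulated markers — natural-log fold-change of
de-logged group means above 0.25 (pseudocount 1e-9 keeps the log total) and
detection in at least 10% of in-group cells — then ranked by Bonferroni-
adjusted p-value, ties broken by descending fold-change and gene ID, and cut
at `n_top` (default 13 per group, a per-cluster budget in line with a
~120-gene marker panel over 9 clusters). All of this is configurable via
`marker_config()`.

## Preprocessing and highly variable genes

`preprocess()` follows the standard pipeline: remove cells with too few
detected genes (default 200) or too high a mitochondrial count fraction
(default 5%, genes identified by ID prefix `MT-`), normalize each cell to a
common library size (default 1e4), `log1p`, and z-score each gene, clipping
at ±10. Zero-variance genes scale to exactly zero rather than NaN so
downstream matrix algebra stays total. QC is idempotent and the defaults
are tuned to real droplet data; for the sparse synthetic data used in the
examples and tests (cells detect roughly 180 of 500 genes) the gene floor
is lowered.

`select_hvgs()` implements the classic binned-dispersion recipe as a
baseline feature selector: mean and dispersion (variance/mean) on de-logged
expression, log-transformed, 20 equal-width bins of log1p mean, z-scores of
log dispersion within bin, selection for mean inside (0.0125, 3) and
dispersion z above 0.5. Single-gene bins receive z = 1 by the convention of
the reference implementation of this recipe. Note the bins are equal-width
over the observed mean range, not equal-frequency — sparsely populated bins
at the range edges are a known sharp edge of the recipe.

## The assembled feature matrix

`assemble_features()` concatenates each split's marker submatrix, splits in
tree pre-order, groups within a split in grouping order, genes in rank
order. A feature belonging to split $S$ is set to exactly 0 for every cell
whose base cluster lies outside $S$'s scope — those cells took no part in
that split's analysis. Zero (not NA) because the matrix feeds distance-based
classifiers and embeddings. A gene selected at several splits appears as
several features, since their masks differ. `render_heatmap()` draws the
same matrix with masked entries white, and `export_umap()` embeds it
(uwot backend, fixed seed, single-threaded, so coordinates are
reproducible).

## Evaluation harness

`knn_within()` performs a stratified 70/30 split (so rare types are present
on both sides) and reports per-class recall of a Euclidean 15-NN classifier
plus the unweighted macro average, which weights rare cell types equally
with abundant ones. `cross_dataset_map()` trains on a labeled reference and
predicts a query dataset that shares the gene namespace and label
vocabulary, choosing feature genes on the reference only. For hierarchical
features the query cells receive unmasked expression over all split
features: masking requires knowing the cell's cluster, which is precisely
the quantity being predicted, so the unmasked representation is the only
information-legal one. The reference keeps its masks. K defaults to 15
(exposed and recorded in every result); the KNN itself is deterministic,
with neighbor ties resolved by distance then training index and vote ties
by label order.

## The synthetic generator

`generate_hier_counts()` emulates the structure the method targets: two
lineages of two subtypes (or arbitrary lineage/leaf trees), disjoint marker
blocks planted per node, counts drawn from a negative binomial with mean
`base_mean * exp(sum of effects on the cell's path)` and dispersion 0.5,
log-normal library-size factors (CV 0.2). The defaults — 100 cells per
leaf, 500 genes, 20 markers per node, lineage effect 1.5, subtype effect
1.0 on the natural-log scale, base mean 0.5 — produce sparse counts whose
lineage signature is strong and shared (the off-diagonal phenomenon) while
subtypes remain separable within a lineage. `batch_shift()` yields a
query-style copy: a seeded gene-wise log-normal factor (amplitude 1.0 in
the mapping experiments) applied multiplicatively, with seeded stochastic
rounding so counts stay integral without biasing low-count genes' means.

What the generator does *not* emulate: dropout beyond what the negative
binomial produces, ambient RNA, doublets, batch effects with cell-type ×
gene interactions, and continuous differentiation gradients. Tests passing
on this generator therefore demonstrate the algorithmic properties —
planted-topology recovery, degenerate collapse, the accuracy ordering of
feature sets — not performance on any particular real dataset.

For the degenerate-case fixtures the planted effect is raised to 2.5:
"mutually distinct clusters" is the design point there, and at effect 1.5
the merge/no-merge decision sits near the sparse-count noise floor rather
than in the cleanly separated regime the fixture is meant to represent.

## Problem sizes and numerical notes

The test-suite and the acceptance script run at desk scale: 400-cell,
500-gene datasets for hierarchy construction (seconds per build; the rank
matrix over a scope is computed once and shared by all candidate
groupings), 10–20 seeded replicates for the stochastic properties, and
exhaustive enumeration oracles only where the combinatorics are tiny
(Wilcoxon layouts up to n = 8, block-mean oracles up to 6 groups). Score
comparisons use a 1e-9 tolerance; the exact-p DP doubles midranks to stay
in integer arithmetic; `wilcox.test` agreement is asserted only on tie-free
data where its exact mode is defined.

## Known limitations

* Greedy agglomeration with a single-step stopping rule can stop at a local
  optimum; no lookahead or restarts are attempted (the trace in every node
  records the full score path for inspection).
* The score compares groupings of the *same* scope; scores at different
  tree depths are not on a common scale.
* `n_top` is fixed per group rather than rebalanced as groups merge, so the
  total marker budget varies across the tree.
* Cluster labels are taken as given; the package neither clusters nor
  refines labels.
* The h5ad interchange format is not read; use the MTX triplet or dense
  TSV paths.
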