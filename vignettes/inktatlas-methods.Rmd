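---
title: "Methods: models, parameters and design choices in inktatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in inktatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inktatlas)
```

inktatlas analyses multi-tissue single-cell RNA-seq atlases of
innate-like T cells together with their paired TCR repertoires. This
vignette is the package's own account of the statistical machinery: what
each stage assumes, which parameters matter, how the synthetic-data
generator is built, and where genuinely open design decisions were made.

## Quality control and normalization

Cells are filtered on two per-cell statistics: the total UMI count and
the mitochondrial UMI fraction (UMIs of genes whose name starts with
`mt-`, case-insensitively, divided by the total). The defaults exclude
cells with *fewer than* 1,000 UMIs or *more than* 10% mitochondrial
fraction. Both comparisons are deliberately strict inequalities — a cell
with exactly 1,000 UMIs and exactly 10.0% mitochondrial content is kept
— and the boundary behaviour is pinned by tests, because off-by-one
differences here silently change every downstream cell count.

Size factors default to library-size factors rescaled to unit mean:
`sf_i = total_i / mean(total)`. Pool-based deconvolution (the summation
approach, via scran) is available as `compute_size_factors(x,
"deconvolution")`; on data without strong composition effects the two
estimators coincide (the package tests this on exactly proportional
expression profiles), and the simpler estimator keeps results exactly
reproducible by hand. Normalization is `log2(count / sf + pseudocount)`
with pseudocount 1, so zeros map to zero and the transform is invertible
given the factors. The pseudocount is configurable; 1 is the
near-universal single-cell convention and the package default.

## Highly variable genes

For each gene the mean `m` and variance `v` of the log-normalized values
are computed, and a loess curve (span 0.3, degree 2, robust `symmetric`
family, direct surface) of `v` on `m` estimates the technical trend
`t(m)`. The biological variance is `v − t(m)`.

A p-value for "biological variance > 0" needs a null distribution for
the relative residual `r = (v − t)/t`. Two facts shaped the design:

* the sampling spread of `r` is strongly mean-dependent (lowly expressed
  genes have unstable variance estimates), so a single global spread
  miscalibrates across the expression range;
* the null of a variance statistic is right-skewed, so a normal
  reference underestimates upper-tail p-values.

The package therefore estimates the residual spread locally — the MAD of
`r` within 20 average-expression bins — and converts it into an
effective degrees of freedom `d = 2 / spread²` for a moment-matched
scaled chi-square reference: `p = P(χ²_d ≥ d·v/t)`. Under an all-null
simulation (2,000 i.i.d. negative binomial genes, 500 cells) the
acceptance suite checks that the raw `p < 0.05` rate lands at the
nominal 0.05 ± 0.02. Genes with Benjamini–Hochberg FDR below `hvg_fdr`
(default 0.05) and positive biological variance are selected. A
degenerate fit (all gene means equal) is a hard error rather than a
silent empty selection.

## Dimensionality reduction, clustering, embedding

The selected HVG submatrix is gene-centered and unit-scaled, and cells
are projected onto the top `n_pcs` principal components (default 15;
studies of this kind alternate between 15 and 20 across subset analyses,
so it is a config field). Each component's sign is fixed by making its
largest-magnitude loading positive, so stored loadings and scores are
reproducible across BLAS implementations.

Clustering builds a k-nearest-neighbor structure in PC space (`snn_k =
20`, exact search), links every pair of cells whose neighbourhoods
(including self) have Jaccard overlap ≥ 1/15, and partitions the
weighted graph by Louvain modularity at `cluster_resolution` (default
0.8) under a fixed seed. The all-pairs shared-neighbor construction
matters: restricting edges to direct kNN pairs makes tight clusters
internally sparse enough that modularity optimization splits them.
Labels are relabelled 0..K−1 by decreasing size. UMAP (15 neighbours,
`min_dist` 0.3, single-threaded layout) is deterministic given the seed;
community detection and UMAP are delegated to igraph and uwot — they are
standard components, and the package's contract for them is determinism
plus recovery on separable data, which the test suite enforces with
generator truth (adjusted Rand index ≥ 0.9 on four subpopulations of 200
cells with 50 markers at log2 fold-change 4).

## Reference projection and mapping ratios

Projection is intentionally simple and fully auditable. Over the
reference HVGs present in the query (coverage below 50% is an error;
missing genes are dropped, never zero-filled), each query cell's Pearson
correlation with every reference cell is computed on the log-normalized
values without further scaling. The `k_project = 5` most-correlated
reference cells are its neighbours — ties broken by reference cell index
— and:

* the projected coordinate is the **unweighted mean** of the neighbours'
  UMAP coordinates (correlation-weighted averaging is a plausible
  alternative; unweighted is the simpler reading of "averaged" and is
  what the tests pin down);
* the assigned subpopulation is the **majority cluster label** among the
  neighbours, ties broken by the higher mean correlation, then the lower
  label index. The categorical call is a design decision of this
  package: coordinate averaging alone never yields a label, and majority
  voting is the least-surprising deterministic rule.

Pearson invariance to per-cell affine transforms of the query (`a + b·x`,
`b > 0`) is verified by property test, and the whole neighbour
computation is checked to 1e−10 against a brute-force double-loop
oracle. Mapping ratios are, per query group, the fraction of mapped
cells assigned to each reference subpopulation (zero-variance query
cells are flagged unmappable and excluded, with a warning). On the
generator's two-tissue design — a reference with a tissue-specific
subpopulation S and a query lacking it — the suite requires the
mapped-to-S ratio below 0.10 and the shared-subpopulation ratio above
0.80 across seeds.

## TCR repertoire analytics

Only contigs flagged productive **and** high-confidence enter the
analysis. Per cell, the highest-UMI contig per chain is selected (ties:
lexicographically smallest CDR3), and cells sharing identical
(Vα, Jα, CDR3α, Vβ, Jβ, CDR3β) form one clonotype; cells missing either
chain stay unassigned and are excluded from denominators. Boolean CSV
fields parse as true only for a case-insensitive `"true"` — 10x emits
`"None"` for unknown, which must not read as productive.

Diversity is the normalized Shannon index (Pielou evenness)
`H = (−Σ pᵢ ln pᵢ)/ln S` over **cells per clonotype** within a group,
with `H = 0` for a single clone by convention. Cell weighting (rather
than UMI weighting) is a documented choice: it matches how clone sizes
are counted in overlap and composition tables. Overlap between groups
reports both the shared-clonotype count and the Jaccard index over
clonotype sets, plus a per-clonotype per-group cell-count composition
table for clones present in more than one group. Spectratypes are CDR3β
length histograms over cells; the modal length (ties toward the shorter
length) defines the 20×L positional amino-acid frequency matrix, whose
columns each sum to 1 — the numeric content of a sequence logo, left to
any renderer.

## Lineage inference and pseudotime

Cluster centroids are means of the 2-D embedding coordinates (PC-space
centroids are available via `space = "pca"`). A minimum spanning tree
with Euclidean weights connects the non-end clusters; candidate edges
are enumerated in lexicographic order so distance ties resolve
deterministically. Each designated end cluster is then attached by a
single edge to its nearest non-end cluster — the simplest construction
that guarantees an "ending" cluster is terminal, even when it sits
geometrically between others; this post-hoc attachment is a deliberate,
documented simplification relative to curve-fitting trajectory tools.
Lineages are the root-to-leaf paths from the start cluster. Pseudotime
projects each cell orthogonally onto the piecewise-linear path through
its lineage's centroids and reports the arc length from the start,
clamped to the path; it is an ordering device, not a model of
transcriptional time. MST weights are verified against an exhaustive
spanning-tree enumeration for up to six clusters, and three-cluster 1-D
gradients must recover the generative order in 5/5 seeds.

## The synthetic-data generator

The generator emulates the data structure the pipeline consumes, with
known truth:

* counts: `NB(mean = baseline · 2^(lfc·is_marker) · libsize, var = μ +
  μ²φ)` with gamma-distributed baselines (shape 0.5, scale 2), φ = 0.4,
  log-normal library-size factors (σ = 0.3), disjoint marker blocks per
  subpopulation, and a designated high-mito cell fraction (5%) whose
  mitochondrial gene means are inflated ×4 — producing realistic QC
  casualties on both filters;
* tissues: a proportion matrix with shared and tissue-specific
  subpopulations; the default two-tissue design gives tissue 1 the
  specific subpopulation A2;
* TCR: every cell carries the invariant mouse iNKT α chain
  (TRAV11/TRAJ18, CDR3α `CVVGDRGSALGRLHF`) plus one β contig drawn from
  its subpopulation's clone pool with Dirichlet(α = 0.8) frequencies
  (clonal expansion); `shared_clone_spec` injects clones into two pools
  and guarantees each injected clone is realized in both subpopulations,
  so engineered overlap is exactly recoverable; a configurable contig
  fraction is flagged non-productive or low-confidence (5% each).

Determinism: one random stream per logical component (gene setup,
counts, library sizes/cell attributes, TCR), each derived from the
master seed, so enlarging one component does not perturb the others.
Identical parameters and seed give bit-identical outputs.

What the generator does **not** emulate: doublets, empty droplets,
ambient RNA, batch effects, gene–gene correlation beyond the marker
programs, nucleotide-level CDR3 structure, or read-level noise. Passing
tests therefore demonstrate correctness of the algorithms under clean
subpopulation structure, not robustness to those artifacts on real data.

## Problem sizes and numerical conventions

The test and acceptance workloads use 300–800 cells and 500–2,000 genes
per scenario with five seeds where stochastic recovery is asserted —
sizes chosen so each scenario exercises the full pipeline while a
complete run of suite plus acceptance script stays in the minutes range
on a laptop. Other conventions: MatrixMarket files are written 1-based
per the standard; trend values are floored at 1e−8 before division;
oracle comparisons use 1e−10 (projection) and 1e−8 (MST) tolerances;
rank-sum tests use mid-ranks with exact enumeration for group sizes ≤ 8
and a tie-corrected normal approximation with continuity correction
above; Bonferroni adjustment is `min(1, m·p)` with `m` the genes tested
within a cluster.

## Known limitations

* Library-size factors ignore composition effects; use the
  deconvolution mode when strong composition shifts are expected.
* The chi-square HVG calibration is tuned to log-normalized NB-like
  data; heavy zero-inflation beyond NB may shift the type-I rate.
* Majority-vote label transfer has no abstention rule: a query cell
  dissimilar to everything still gets the label of its best (possibly
  poor) neighbours; inspect neighbour correlations before trusting
  ratios.
* MST lineages are topology only — no branch curves, no uncertainty on
  pseudotime.
* The marker rank-sum test treats cells as exchangeable replicates;
  with multi-sample designs a pseudobulk approach is more conservative
  and is out of scope here.
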