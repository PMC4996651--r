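---
title: "Lineage-guided PCA for developmental atlases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-guided PCA for developmental atlases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgpca)
```

## Motivation

A transcriptome atlas sampled across many embryonic organs and tissues holds
two kinds of structure: expression shared among developmentally related
sites, and expression peculiar to a single site or even a single replicate.
Ordinary PCA mixes the two, and on such data tends to spend its leading
components on the one or two most biochemically extreme tissues. LgPCA
injects the missing prior — the developmental lineage — as a sample-by-sample
proximity weighting, separating lineage-coherent ("global") from
heterogeneity ("local") axes.

## The lineage model

The guide tree is user knowledge, not something inferred from the data: a
rooted topology whose leaves are the RNA-seq samples, with replicate samples
attached as sister leaves under their tissue node. Branch lengths are
ignored throughout; only the nesting of clades matters. `read_lineage_tree()`
enforces at least three leaves, unique labels and multifurcating internal
nodes (single-child nodes are collapsed at parse time — they would
contribute a direct-descendant count of 1 to every path product, a no-op
that only violates the node invariant).

Proximity between two leaves is the Abouheif path product: the reciprocal of
the product of direct-descendant counts over the internal nodes connecting
them. Sister leaves under a binary node get 1/2; leaves separated by many
polytomies get small values. Rows are then normalized to sum to 1, giving
the weighting matrix `W` (zero diagonal). We expose `variant = "raw"` for
the unnormalized symmetric form; the diagonal-occupied variant of the
original permutation test is not provided because the pipeline never
consumes it and its normalization is not uniquely fixed by the proximity
definition above.

On a star tree every path crosses the single root, so `W` is uniform —
a useful degenerate case, because there LgPCA must collapse to standard PCA
(see below).

## The LgPCA criterion

With `X` the samples-by-genes matrix, column-centered and by default
column-scaled to unit (population) variance, and `Ws = (W + W')/2`:

$$ H = \tfrac{1}{n} X^\top W_s X, \qquad H u_k = \lambda_k u_k . $$

Axes are ordered by signed eigenvalue, descending, and each satisfies the
Moran decomposition $\lambda_k = \mathrm{var}(y_k)\, I(y_k)$ with
$y_k = X u_k$, $\mathrm{var}(y) = \sum_i y_i^2 / n$ and
$I(y) = y^\top W_s y / y^\top y$. The tests verify this identity to 1e-10
relative on every fit. Positive $\lambda$ means related samples score
similarly (global structure); negative $\lambda$ means they diverge (local
structure). For an atlas of 15 tissue pairs plus a stem-cell pair (32
samples) a full-rank matrix yields 31 axes; in our synthetic atlas the
global/local split suggested by the eigenvalue sign lands at 15 vs 16,
matching the 15-global-axis convention we use as the
`partition_axes(fit, 15)` default in examples.

Numerical choices:

* **Duality.** With thousands of genes, `H` is never formed. From the thin
  SVD `X = U D V'`, the nonzero spectrum of `H` equals that of the small
  matrix `M = D (U' Ws U) D / n`, and axes are `V Q` for eigenvectors `Q` of
  `M`. Tests pin this to the direct gene-space eigendecomposition at
  n = 10, p = 40 (1e-8 agreement); the trick is an optimization, not a
  semantic change.
* **Rank.** Singular values below `1e-12 * d_max` are dropped; axes with
  `|lambda| <= 1e-9 * max|lambda|` are dropped. Generic centered data with
  n samples keeps exactly n - 1 axes.
* **Scaling.** Atlas-scale data (quantile-normalized counts) spans
  orders of magnitude across genes, so unit-variance scaling is the default
  (`scale. = TRUE`), with the unscaled mode supported and equally tested.
  Genes constant across samples cannot be scaled and are zeroed with a
  warning.
* **Sign.** The sign of each axis is mathematically arbitrary; we fix it by
  making the largest-magnitude loading positive, purely for reproducibility.
* **Star-tree limit.** With uniform proximity,
  `X'(J - I)X = -X'X` on centered data, so
  `lambda_k = -lambda_k^PCA / (n - 1)`: all eigenvalues negative, axes equal
  to PCA axes. The test suite asserts both.

Downstream of the fit, `extreme_genes()` takes the k most positive and k
most negative loadings per axis (ties broken lexicographically by gene ID —
the tie rule is our fixed convention, chosen so re-runs are bit-stable), and
`loading_gene_set_test()` runs a two-sided Wilcoxon rank-sum test of a gene
set's loadings against the remaining genes, reporting the rank-biserial
correlation as effect size and skipping sets of 10 or fewer genes (strict
inequality, following the ">10 genes" convention for annotated sets).

## Expression preprocessing

Quantile normalization forces every sample onto the common reference
distribution whose r-th value is the mean of the samples' r-th order
statistics. Ties receive the mean of their tied ranks' reference values
(the tie policy of the widely used implementations; the method definition
itself is silent on ties). The operation leaves column sums equal, makes
sorted columns identical in the absence of ties, and is idempotent — all
asserted in tests, alongside agreement with an independent reference
implementation (limma) to 1e-12.

Tau summarizes tissue specificity per gene on per-tissue mean normalized
counts: 0 for flat profiles, 1 for single-tissue expression. We compute it
on linear-scale means by default, because the atlas convention is means of
normalized read counts; a `log2_transform` flag applies `log2(x + 1)` first
for users who prefer compressed profiles. Genes whose tissue means are all
zero have an undefined Tau and are reported `NA` rather than forced to
either pole. Tau on a single tissue is an error (the `N - 1` denominator
vanishes).

`prefilter_counts()` drops caller-specified exclusions (typically Y-linked
genes and XIST, supplied as a list so the operation needs no annotation) and
genes with fewer than 100 reads in total; a gene with exactly 100 stays.

## Metagene extraction

`nmf_brunet()` minimizes the generalized Kullback-Leibler divergence with
the Brunet variant of the multiplicative updates, from random uniform
`U(0, max(V)/r)` initialization under a mandatory seed. The KL trace is
recorded every iteration and must be non-increasing (tolerance 1e-9); on an
exactly low-rank matrix it reaches machine-precision zero at the true rank.
Iteration stops at `max_iter` or when the sample connectivity matrix
(co-membership under argmax-coefficient assignment — the standard assignment
for this consensus method) has been stable for 40 consecutive checks taken
every 10 iterations; fixed-iteration behaviour is available via
`stall_checks = Inf`.

`consensus_select_rank()` averages run connectivity into a per-rank
consensus, computes the cophenetic correlation between the consensus
distance and its average-linkage dendrogram, and picks the rank with the
maximal coefficient ("maximal cophenetic" read as the maximal cophenetic
correlation coefficient, the standard criterion of the reference NMF
implementation). Two behaviours are worth knowing:

* The criterion needs enough runs. With very few runs per rank, a rank-2
  factorization of three clean blocks can merge the same pair in every run
  and tie the true rank at a coefficient of 1; across the 50 runs per rank
  used at analysis scale (and in the acceptance checks) the merge choice
  varies with initialization and the spurious rank destabilizes. Scaled-down
  unit tests therefore check recovery at run counts where the criterion is
  informative.
* A matrix with no between-sample structure (every gene flat) makes rank
  selection meaningless; it is flagged (`stable = FALSE`) with a warning
  rather than silently reported.

Gene-to-metagene assignment uses the row-normalized basis weight ("basis
contribution", formalized here as `W[g,k] / sum_j W[g,j]` since the analysis
convention does not define it) with a strict 0.8 threshold; any threshold
above 0.5 makes the sets disjoint by construction. `metagene_score()` scores
external samples as the mean `log2(x + 1)` expression of each set, z-scored
across metagenes within a sample — a declared stand-in for the enrichment
display of the original analyses, which is not otherwise specified.

## Novel transcript classification and naming

Assembled transcript models are compared with a reference annotation using
simplified single-letter class codes in the fixed priority order
j > e > p > o > x > i > u (the upstream tool's tie-breaking is
undocumented, so the order is our convention): exact same-strand intron
match (j), unspliced pre-mRNA-like containment (e), same-strand 3' run-on
within 2 kb (p) — all discarded — then same-strand exonic overlap (o),
antisense exonic overlap (x), wholly intronic (i) and unknown/intergenic
(u), which are retained. Retained transcripts get a positional class:
BI when the TSS lies within 1 kb (inclusive) of an annotated TSS on the
*opposite* strand — the strand requirement is our reading of bidirectional
(divergent-promoter) geometry — else AS for x, OT for o, LINC otherwise.
A coding score above 0.2 flags TUCP; purely intergenic TUCPs are named as
TUCP, while gene-associated classes keep their positional name and carry
the TUCP flag as a dual label. LINC/TUCP transcripts share one T-number
sequence per chromosome ordered by TSS coordinate (`HE-LINC-C7T121`);
BI/AS/OT are named by the associated gene symbol (`HE-BI-GATA4`), the
association being the nearest opposite-strand TSS for BI and the gene with
the largest exonic overlap for AS/OT, ties lexicographic.

`dedupe_and_filter()` clusters same-strand exonic overlap by single linkage
into loci — strand-aware, because an antisense pair is two biological units —
keeps the longest transcript per locus (ties: more exons, then smaller ID)
and drops transcripts of 200 bp or less (strict). Coordinates are held as
1-based closed GRanges internally, the native convention of the R interval
stack, with GTF conversion confined to the I/O boundary; every stated
boundary (2 kb, 1 kb, 200 bp, 1 Mb) is exercised at its exact edge by the
toy fixture. `neighborhood_correlation()` correlates each final transcript
with every annotated gene whose TSS (either strand) lies within 1 Mb
inclusive, using Pearson correlation on `log2(x + 1)` — the correlation
scale is our choice; only "correlation (r)" is conventionally specified —
and reports nearest gene, best-|r| gene and the window mean distance as the
random expectation.

## What the synthetic data does and does not emulate

`simulate_lineage_counts()` draws per-gene baseline log2 means
(N(4, 1.5^2), i.e. typical bulk depth), evolves them by independent
Gaussian steps (sd 0.3) along each tree edge — giving counts the
tree-structured covariance the method assumes — plants clade-restricted
modules as additive log2 effects, and samples negative-binomial counts
(dispersion 0.05) with log-normal library factors (sdlog 0.1). These
defaults are the study conditions of all tests and of the acceptance
script; they were chosen once as realistic bulk RNA-seq magnitudes. The
default tree has 32 leaves: 15 tissue pairs under ectoderm/mesoderm/endoderm
clades (with a foregut subclade) plus a pluripotent pair — mirroring the
atlas shape that yields 31 components.

The generator does not emulate batch effects, varying replicate counts,
gene-length or GC biases, correlated gene-gene noise beyond the tree, or
read-level artifacts. Passing tests therefore demonstrate the correctness
of the algorithms under the stated generative model, not robustness to
every failure mode of real embryonic RNA-seq. Likewise the toy annotation
is a minimal, hand-placed set of coordinates covering every classification
outcome and boundary — it validates rules, not genome-scale performance.
`simulate_block_counts()` provides the NMF ground truth (disjoint gene and
sample blocks, mean 100 on-block vs 5 off-block).

## Problem sizes and determinism

Unit tests run on reduced instances (hundreds to a few thousand genes;
consensus at 4-20 runs per rank); the acceptance script uses the atlas
shape at 5,000 genes and the full 50-run consensus over 20 seeded repeats,
completing in minutes on one CPU. Every stochastic step takes an explicit
seed, derived seeds stay within the 32-bit range, and generators restore
the caller's RNG state, so whole-pipeline runs are bit-reproducible
(`run_pipeline()` writes the seed, parameters and input checksums into its
manifest).

## Known limitations

* The guide tree is a fixed input; no support for inferring it or for
  weighting by branch lengths (deliberately, as the method is
  topology-only).
* The class-code rules are a simplified reimplementation sufficient for the
  retained/discarded split and the positional nomenclature; exotic cases
  (read-through beyond the 2 kb rule, UTR-extension rescue) are out of
  scope.
* Gene-set testing is flat (no ontology-graph elimination), and coding
  potential is consumed as a precomputed score column, never recomputed.
* `metagene_score()` is a reasonable enrichment summary but not a validated
  reproduction of any particular published display.
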