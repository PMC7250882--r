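---
title: "Methods: cross-species co-expression conservation with coexmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species co-expression conservation with coexmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmap)
library(dplyr)
```

## The question the package answers

Insect body plans share organs — gut, muscle, brain, gonads — whose
transcriptomic programmes may be far older than any one lineage. coexmap
asks, for a pair (or panel) of species with bulk expression data across
tissues and life-cycle stages: *which co-expression modules are conserved
across species, which genes are tissue-specific, and at which point in the
phylogeny did the underlying gene families arise?* The motivating use case
is comparing an aquatic hemimetabolous insect (with gills and developing
wing pads among its sampled organs) against a distant holometabolous
relative, to test whether organs such as wings run on anciently conserved
gene programmes.

The pipeline has five analytical stages, each usable on its own:

1. **Normalization** (`compute_crpkm()`): counts are converted to cRPKM —
   reads per kilobase of *uniquely mappable* positions per million mapped
   reads. The per-sample mapped total is the column sum of the supplied
   count matrix, so the computation is self-contained; the mappable length
   (in kb) is supplied per gene. Replicates are averaged arithmetically per
   condition (`average_replicates()`).
2. **Soft clustering of stage profiles** (`fuzzy_cmeans()`): standardized
   condition profiles are clustered with fuzzy c-means, giving each gene a
   membership in every cluster. Hard assignment is argmax membership;
   *core genes* are those whose winning membership reaches a threshold
   (default 0.5); each cluster is labelled by the condition at its centre's
   peak.
3. **Co-expression modules** (`adjacency()`, `tom_similarity()`,
   `detect_modules()`): a weighted correlation network per species —
   unsigned soft-thresholded adjacency `|cor|^beta`, topological overlap,
   average-linkage clustering on `1 - TOM`, and a static cut.
4. **Cross-species conservation** (`overlap_matrix()`): modules are mapped
   into orthogroup space and every cross-species module pair is scored
   with an upper-tail hypergeometric test; conserved cores are extracted
   with `conserved_core()`.
5. **Specificity and gene age** (`tau_table()`,
   `shared_tissue_genes()`, `assign_phylostrata()`, `enrich_terms()`,
   `enrich_phylostrata()`): the tau index, the shared-tissue filter, and
   phylostratigraphic enrichment by two-sided Fisher tests.

## The central statistic: orthogroup-mediated module overlap

Genes cannot be compared one-to-one across distant species; gene *families*
(orthogroups, in the OrthoFinder sense) can. A module `M_A` of species A is
represented by the set `O(M_A)` of orthogroups its member genes belong to —
a family expanded by lineage-specific duplication counts once, so overlap
is not inflated by paralog bursts. For modules `M_A`, `M_B`:

* the universe `N` is the number of orthogroups with at least one
  *analysed* gene in **both** species. Unassigned (module 0) genes count
  towards `N` — they could have been drawn — but form no module. The test
  thus conditions on the background actually available to both analyses.
* with `K = |O(M_A)|`, `n = |O(M_B)|`, `x = |O(M_A) ∩ O(M_B)|`, the
  reported p-value is `P[X >= x]` for `X ~ Hypergeometric(N, K, n)`.

P-values are reported raw by default, matching the practice of reading the
full module-pair matrix as a heatmap of raw significance; a
Benjamini–Hochberg column is available (`adjust = TRUE`). The tail is
accumulated in log space, so the astronomically small p-values produced by
genuinely conserved module pairs do not underflow.

The universe definition is a genuine design choice: the alternative — all
orthogroups in the table — makes every test look more significant by
padding the background with families neither analysis could have drawn. We
condition on the shared analysed background and document it here rather
than exposing an option, because the two choices answer different
questions and only the conditional one matches the null of "random draws
from what both species analysed".

## Exact tests

`hypergeom_upper_tail()` and `fisher_two_sided()` are computed from
log-binomial coefficients (`lchoose`). The two-sided Fisher p is the sum
of probabilities of all tables, at fixed margins, whose point probability
is at most the observed one (with a `1e-7` relative tolerance for
floating-point ties) — the convention of `fisher.test`. Both functions are
verified in the test suite against full-support enumeration: exhaustively
for every parameterization with `N <= 30`, and on random instances up to
`N = 100`, alongside `phyper` and `fisher.test` as independent references.

## Fuzzy c-means: parameters and numerical choices

The updates are the classical alternating ones,
`u_ij = [sum_k (d_ij/d_ik)^(2/(m-1))]^{-1}` and membership-weighted
centres, stopping when the largest membership change is below `tol`
(default `1e-6`). Numerical details that matter:

* **Fuzzifier `m = 1.25`.** Standardized expression profiles are
  high-dimensional and noisy; small fuzzifiers keep memberships
  informative (values near 2 wash them out). The objective-function trace
  is recorded and non-increase is asserted in tests.
* **Initialization from `c` distinct data profiles** under a caller seed,
  rather than random memberships: reproducible and typically convergent in
  tens of iterations. Like any single-start local optimizer it can stick;
  the benchmark and tests either use a fixed adequate seed or take the
  best objective over a few seeds, which is also the sensible practice on
  real data.
* **Zero-distance rule**: a gene coincident with a centre takes membership
  1 there, 0 elsewhere, avoiding 0/0 in the update.
* **Cluster count `c`** is mandatory, with no heuristic: on real stage
  series one chooses it from the design (a genome-scale 8-stage analysis
  may use 30 or more clusters; the synthetic benchmark uses one cluster
  per planted class).

## Module detection choices

* **Unsigned network, `beta = 6`** — the common defaults when the sign of
  co-regulation is not the target; `pick_beta()` implements the usual
  scale-free-fit advisory (smallest power with R² ≥ 0.8).
* **Static cut** at a fixed fraction (default 0.9) of the tallest merge,
  with a minimum module size of 10, instead of dynamic tree cutting: the
  static cut is fully specifiable, deterministic, and testable; dynamic
  cutting is an extension point. Modules are renumbered by decreasing
  size; label 0 means unassigned.
* **Variance filtering**: for genome-scale data a coefficient-of-variation
  filter (`filter_by_cv()`, threshold 1, n−1 standard deviation) reduces
  tens of thousands of genes to the variable subset before network
  construction. On the synthetic benchmark (hundreds of genes) module
  detection runs on the full cRPKM matrix: Pearson correlation does not
  require high CV, and a two-tissue module sitting near the CV threshold
  should not drop out of the analysis because of a filter designed for
  data reduction. The filter remains in the soft-clustering path, where
  profile standardization would otherwise amplify flat noise genes.

## Tau and the shared-tissue filter

Tau is `sum(1 - x/max(x)) / (n - 1)` on condition-averaged, untransformed
cRPKM: 0 for uniform expression, 1 for single-condition expression,
undefined for all-zero genes. It is scale-invariant and rises as
expression specializes; genes with `tau > 0.8` are called specific.

The shared-tissue filter asks which *second* tissue co-expresses genes
biased to a focal tissue (e.g. wing pads). For each gene the second tissue
is its highest-expressed non-focal condition; the gene passes when the
test-group minimum (focal and second) reaches `min_expr = 20` cRPKM and
every remaining condition is at least `margin = 30%` below that minimum.
"At least 30% lower" is interpreted against the *test-group minimum* — the
strictest reading that uses only the named quantities; since reasonable
alternatives exist (relative to the test-group mean, or to each member),
the thresholds are plain arguments and the rule is documented here as
policy rather than hidden.

## Phylostratigraphy

A gene's phylostratum is the node, on the root-to-focal path, where its
orthogroup first appears: the MRCA of the focal species and all species
with a member in the family. Genes outside any family (or in focal-only
families) are species-specific — the standard youngest-stratum assignment
for singletons. Per-node *gains* count families originating at each node
(each family exactly once, so gains partition the table); a gain is a
*core* gain when every sampled leaf below the origin retains the family.
"Core" has no unique field definition; presence-in-all-descendants is the
strictest one and is what the generator's truth tables encode. Note that
gene loss can only make a family look *younger* than its true origin
(the MRCA of survivors is never above the true origin node); the test
suite asserts exactly this one-sided relation under simulated loss.

## What the synthetic generator does and does not emulate

`simulate_dataset()` draws an orthogroup scaffold on a species tree
(origin node sampled root-heavy, per-descendant retention, optional
paralog copies), plants co-expression module pairs whose orthogroups are
shared between the first two species at a configurable fraction φ, plants
strictly tissue-specific genes (expression zero outside the target
tissue), and generates counts by Poisson thinning of
`exp(baseline + effect + N(0, noise_sd²))` to a fixed library size —
the simplest count model under which cRPKM is meaningful; a negative
binomial dispersion is available.

Defaults describe the benchmark conditions used throughout the tests: two
species, 350 families (about 300 genes per species), eight tissues × two
replicates, four planted module pairs of 40 genes at φ = 0.8 with a
two-log-unit peak effect, 15 tissue-specific genes, log-noise 0.3. One
planted module peaks jointly in wing pads and gills, emulating a
co-expression programme shared by two organs; its recovery is what makes
the wing-pad/gill sibling check on the sample dendrogram meaningful.
Effect size (2 log-e units ≈ 7-fold) and replicate noise (0.3, i.e. ~35%
CV) are free parameters chosen as ordinary values for strong tissue
programmes in bulk RNA-seq; they are not estimates of any particular
dataset.

What the generator does **not** emulate: mappability structure (lengths
are i.i.d. log-normal), compositional library effects beyond the per-sample
renormalization that Poisson thinning induces, correlated noise between
replicates, batch effects, partial module overlap *within* a species, and
unequal module expression between partner species. Passing the
planted-truth benchmark therefore shows the machinery is correct and
well-calibrated at realistic signal-to-noise, not that genome-scale
results from any real dataset are reproduced.

## Problem sizes and determinism

The test suite and the acceptance script run on hundreds of genes and tens
of samples per dataset — sizes at which every stage is exact or
single-seed deterministic and the full suite completes in well under a
minute on one CPU. All randomness flows from explicit seeds: the
simulation configuration carries one, fuzzy c-means takes one, and the
benchmark derives per-dataset seeds from a single integer, so identical
inputs give byte-identical outputs.

## Known limitations

* Fuzzy c-means is a single-start local optimizer; pathological seeds can
  merge well-separated clusters. Use several seeds and keep the best
  objective when `c` is large.
* The static tree cut has no notion of nested modules; very unequal module
  densities can fragment a loose module before a tight one splits.
* Orthogroup-space overlap treats a family as one vote regardless of size;
  a module dominated by one giant family is conservatively represented.
* Flat term enrichment ignores ontology topology; DAG-aware algorithms
  (elim/weight) are out of scope, as are module-preservation statistics,
  eigengene analysis, and differential expression.
* The spanning interface is R functions plus `run_pipeline()`; there is no
  shell executable.
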