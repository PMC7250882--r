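# coexmap

Cross-species co-expression module conservation, tissue specificity and
gene-age assignment for developmental transcriptomes.

## The problem

Distantly related species cannot be compared gene by gene, but their
tissues and life stages can be compared *programme by programme*: detect
co-expression modules in each species, map every module into gene-family
(orthogroup) space, and ask whether two modules share more families than
random draws from the common background would allow. coexmap implements
that comparative pipeline end to end for bulk expression data across
tissues and stages — the setting of questions like *"do insect wings run
on a gene programme older than winged insects themselves?"* — together
with the tissue-level statistics that surround it.

## What it computes

- **cRPKM normalization** — reads per kilobase of uniquely mappable
  positions per million mapped reads, with replicate averaging
  (`compute_crpkm()`, `average_replicates()`).
- **Fuzzy c-means soft clustering** of standardized stage profiles with
  memberships u<sub>ij</sub>, hard assignments, membership-thresholded
  *core genes*, and per-cluster peak stages (`fuzzy_cmeans()`,
  `core_genes()`, `peak_condition()`).
- **Weighted co-expression modules** — unsigned adjacency |cor|<sup>β</sup>,
  topological overlap, average-linkage clustering with a static cut
  (`adjacency()`, `tom_similarity()`, `detect_modules()`).
- **Cross-species module conservation** — for modules M<sub>A</sub>,
  M<sub>B</sub> with orthogroup sets of sizes K and n, overlap x, in a
  universe of N orthogroups analysed in both species, the raw upper-tail
  hypergeometric p-value P[X ≥ x] (`overlap_matrix()`), plus shared-core
  extraction (`conserved_core()`).
- **Exact statistics** — log-space hypergeometric tails, two-sided
  Fisher's exact test (sum of ≤-likely tables), Benjamini–Hochberg
  (`hypergeom_upper_tail()`, `fisher_two_sided()`, `benjamini_hochberg()`).
- **Tau tissue specificity** — τ = Σ(1 − x/max x)/(n − 1) with a 0.8
  specificity call (`tau_table()`, `specific_genes()`), and the
  **shared-tissue filter**: genes expressed in a focal tissue plus exactly
  one other (test-group minimum ≥ 20 cRPKM, everything else ≥ 30% lower;
  `shared_tissue_genes()`).
- **Phylostratigraphy** — gene ages as the tree node where each family
  first appears, per-node family gains and core gains, and Fisher
  enrichment of strata or flat annotation terms (`assign_phylostrata()`,
  `count_gains()`, `enrich_terms()`, `enrich_phylostrata()`).
- **A synthetic multi-species generator** with planted module pairs,
  planted tissue-specific genes, an orthogroup/phylogeny scaffold and
  full ground truth (`simulate_dataset()`, `simulate_timecourse()`,
  `write_fixture()`), so every stage is testable without downloads.

Results are tibbles (or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods), so everything composes with dplyr and ggplot2.

## Worked example

Simulate a two-species dataset under the default study conditions (about
300 genes per species, 8 tissues × 2 replicates, four planted module
pairs of 40 genes sharing 80% of their families, one of them peaking
jointly in wing pads and gills), then test module conservation:

```r
library(coexmap)
library(dplyr)

d <- simulate_dataset(simulation_config(seed = 1))

crA <- compute_crpkm(d$expression$spA, d$lengths$spA)
crB <- compute_crpkm(d$expression$spB, d$lengths$spB)
modA <- detect_modules(tom_similarity(adjacency(crA, beta = 6)), species = "spA")
modB <- detect_modules(tom_similarity(adjacency(crB, beta = 6)), species = "spB")

og <- filter_min_species(d$orthogroups, k = 2)
ov <- overlap_matrix(modA, modB, og, "spA", "spB")
ov |> tidy() |> arrange(p_raw) |> head(5)
#>   module_a module_b     K     n     x     N    p_raw
#> 1        4        1    36    40    33   251 6.14e-31
#> 2        1        3    39    38    32   251 1.18e-27
#> 3        3        4    38    39    32   251 1.18e-27
#> 4        5        2    39    39    32   251 6.37e-27
#> 5        6        6    21    13     6   251 1.95e- 4
```

Four module pairs share ~32 of their ~39 families against a universe of
N = 251 orthogroups — the planted orthologous pairs, at p < 10⁻²⁶; the
next-best pair is eight orders of magnitude weaker. The shared-tissue
filter on the same data finds the planted wing-pad/gill programme:

```r
av <- average_replicates(crA, d$metadata)
shared_tissue_genes(av, focal = "wing_pad")
#> Shared-tissue filter (focal: wing_pad | min expression: 20 | margin: 0.3 )
#> 40 of 327 genes pass; second tissues:
#>   second_condition n_genes
#> 1 gill                  40
```

i.e. all 40 passing wing-pad-biased genes have gills as their second
tissue. `specific_genes(av)` likewise recovers the planted
tissue-specific genes at τ > 0.8, and `verify_worked_examples()` checks
the package's integer-ratio arithmetic (e.g. 42 of 98 → 43%) against its
reported values — all five rows report `pass = TRUE`.

`run_pipeline(fixture_dir, out_dir)` chains all stages on files written
by `write_fixture()` and records a JSON provenance sidecar.

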