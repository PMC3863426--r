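# duplirep

Links three layers of genome biology for protein-coding genes: the
**evolutionary age of gene duplicates**, **copy-number variability** in a
population panel, and **DNA replication timing** in dividing cells. The
recurring observation in mammals is that recently duplicated genes cluster
in copy-number-variable (CNV), late-replicating regions, while ancient
duplicates and singletons sit in early-replicating, copy-stable territory.
`duplirep` provides the full analysis pipeline behind that observation —
plus a synthetic-data generator that plants known truth at every layer, so
each stage can be verified by recovery rather than taken on faith.

## What it computes

**Duplication age (phylostratification).** Every focal-species gene is
dated from its annotated gene-family tree (Newick/NHX with `D`, `S`, `DCS`
tags). Walking from the gene's leaf toward the root, each duplication node
with consistency score *s* is judged against a threshold *t* (default 0.3):

- *s* > *t* — the gene is a **PDG** (protein-coding duplicated gene); its
  age class is the taxonomic level of that node, looked up in an ordered
  timeline of ancestral taxa (14 classes for human, Bilateria → *Homo
  sapiens*; 13 for mouse; Euarchontoglires collapses into Eutheria);
- *s* = 0 — the node is treated as a reconstruction artifact and the walk
  continues to the previous (older) duplication node;
- 0 < *s* ≤ *t* — the age is unclear; the gene is **UNASSIGNED**.

Genes whose walk finds no acceptable duplication node — or whose evidence
predates the oldest timeline class — are **singletons**.

**CNV status.** A gene is copy-number variable when ≥ 4 or < 2 copies occur
in at least 2 individuals of the panel; genes shorter than 1 kb and (by
default) non-autosomal genes are excluded before calling.

**Replication timing.** Per-sample probe log-ratios are rank-transformed
(rank 1 = earliest), each probe takes its median rank across samples, each
gene takes the probe nearest its center (dropped beyond 10 kb), and genes
are sorted into a genome-wide *order of replication*.

**Chromosomal regions.** Genes within 5 Mb of the centromere are
pericentromeric, within 5 Mb of a telomere subtelomeric, the rest
interstitial (centromere wins on overlap).

**Statistics.** Chi-squared enrichment across phylostrata, two-proportion
comparisons, Wilcoxon rank-sum on replication order, Spearman rank
correlation of age class vs replication order (overall and per region), and
fold enrichment of CNV duplicates near centromeres/telomeres.

## Worked example

```r
library(duplirep)

sim    <- simulate_dataset(sim_config(seed = 42, n_genes = 2000))
report <- run_full_analysis(sim)
report
#> <duplirep_report>
#>   genes: 2000 (1404 PDG, 596 singleton, 0 unassigned)
#>   CNV genes: 260 (39 excluded from calling); with RT: 2000
#>   age-RT Spearman rho = 0.951 (p = 0, n = 1404)
#>   15 tests; see $tests, $cnv_by_age, $master
```

The simulation plants CNV enrichment in the five youngest (primate-era)
age classes and a replication-timing gradient of 0.2 log-ratio units per
age-class step; the report recovers exactly the planted structure:

```r
dplyr::select(tidy(report), comparison, p_value, effect)
#> # A tibble: 15 × 3
#>    comparison                                 p_value  effect
#>  1 cnv_fraction_by_age_class                5.87e- 93 NA
#>  2 cnv_proportion_pdg_vs_singleton          4.90e- 21  0.157
#>  3 rt_cnv_vs_noncnv_all                     4.55e- 83  0.743
#>  6 rt_cnv_vs_noncnv_young_pdg               6.52e-  7  0.263
#>  7 rt_cnv_vs_noncnv_old_pdg                 1.71e-  1  0.164
#>  9 rt_vs_age_all_pdg                        0          0.951
#>  ...
```

Reading the rows: CNV fraction varies strongly across age classes
(chi-squared p ≈ 6e-93); duplicated genes carry CNVs 15.7 percentage points
more often than singletons; CNV duplicates replicate later than copy-stable
ones among *young* duplicates (rank-biserial 0.26, p ≈ 7e-7) but not among
old ones (p = 0.17); and the age-class → replication-order Spearman rho is
0.95 with the generator's (deliberately strong) planted gradient.
`autoplot(report)` draws the CNV-fraction-by-age bar chart,
`autoplot(report, type = "rt_by_age")` the replication boxplots, and
`glance(report)` gives a one-row summary.

Every stage is exposed on its own: `parse_gene_tree()`,
`assign_duplication_age()`, `call_cnv_genes()`, `median_probe_rank()`,
`assign_gene_rt()`, `classify_gene_region()`, and the test wrappers
(`chi_squared_independence()`, `wilcoxon_rank_sum()`,
`spearman_correlation()`, `fold_enrichment()`, `two_proportion_test()`).
`write_simulation()` / `read_pipeline_inputs()` round-trip all inputs
through the on-disk formats (NHX files, BED6, TSV).

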