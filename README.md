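# kdm5caml

An R package that reimplements, as tested and fully simulated-data-backed
code, the computational analyses used to identify the H3K4me2/3 demethylase
**KDM5C** as a tumor suppressor in acute myeloid leukemia (AML). It is aimed
at computational biologists who want to reproduce, stress-test or reuse the
individual statistical steps of that style of study — pooled shRNA screen
scoring, promoter chromatin-state classification, knockdown differential
expression, coupled ChIP/RNA integration, histone-PTM ratio statistics and
expression-stratified clinical statistics — without access to the deposited
sequencing, proteomics or patient data.

## What it computes

* **Pooled shRNA screen scoring** (`screen_pipeline()`): counts-per-million
  normalization with pseudocount, per-hairpin mean log2(output/input) fold
  change averaged over replicates, ranking of the direction-filtered
  hairpins, and the hit rule *gene is a hit if ≥ 2 of its shRNAs rank within
  the top 25th percentile of enriched (or depleted) shRNAs*, i.e.
  rank ≤ ⌊0.25·n⌋.
* **Chromatin states** (`mark_presence()`, `classify_promoters()`): mark
  presence by a background-quantile threshold on replicate-mean TPM, then
  the standard partition — H3K4me3 only → *active*, H3K27me3 only →
  *repressed*, both → *bivalent*, neither → *unmarked*.
* **Differential regions** (`differential_regions()`): log2 ratio of
  replicate-mean TPM (KD vs control, 0.5 pseudocount) with an
  empirical-Bayes moderated t on log2(TPM+0.5) and Benjamini–Hochberg FDR,
  plus strand-aware TSS metaprofiles (`tss_metaprofile()`).
* **Differential expression classes** (`de_pipeline()`): Welch t on
  log2 CPM per knockdown arm, then the either-arm rule — *up* (or *down*)
  if FDR < 0.05 in at least one arm with concordant fold-change signs,
  *neutral* otherwise (discordant significant arms are flagged).
* **Integration panels** (`signal_change_by_class()`,
  `occupancy_by_group()`, `expression_fc_by_state()`,
  `state_fractions_by_class()`, `nearest_gene_enhancers()`,
  `attribute_by_class()`, `stage_profiles_by_class()`): notched-boxplot-style
  stratified comparisons with two-sided Mann–Whitney tests, promoter-state
  fractions per class, nearest-TSS enhancer assignment, and
  differentiation-stage Spearman trends (LSK → pre-GM → GMP → Gr → Mono).
* **PTM ratios** (`ptm_ratio_table()`): per-modification KD/control
  abundance ratios with two-tailed t-tests, unadjusted by default.
* **Clinical statistics** (`fisher_exact()`, `km_curve()`, `logrank()`,
  `median_stratify()`, `filter_min_followup()`, `mutation_enrichment()`,
  `expression_by_status()`, `survival_stratified()`): Fisher's exact test
  (two-sided, point-probability rule), Kaplan–Meier product-limit curves,
  the two-group log-rank test, strict above-median expression splits
  (single gene, or KDM5C+KDM5D summed for males), a ≥ 6-month follow-up
  filter, and quartile mutation-enrichment Fisher tests — all implemented
  from first principles and cross-checked against independent oracles.
* **Synthetic data** (`sim_config()`, `simulate_all()`,
  `write_simulation()`): every pipeline input with planted ground truth —
  an 849-shRNA / 315-gene library with negative-binomial counts, a toy
  epigenome with planted states and KDM5C occupancy, linked expression
  counts, stage matrices, a two-sex patient cohort and PTM tables.

## Worked example

```r
library(kdm5caml)
cfg <- sim_config(seed = 1)   # the default study conditions
sim <- simulate_all(cfg)

pipe <- screen_pipeline(sim$screen$counts, sim$screen$samples,
                        sim$library, "enriched")
head(pipe$gene_calls, 5)
#>       gene n_shrnas n_qualifying  hit direction
#> 1 gene_008        3            3 TRUE  enriched
#> 2 gene_055        3            3 TRUE  enriched
#> 3 gene_066        3            3 TRUE  enriched
#> 4 gene_076        3            3 TRUE  enriched
#> 5 gene_098        3            3 TRUE  enriched

de <- de_pipeline(sim$expression$counts, sim$expression$samples)
table(de$de_class)
#>    down neutral      up
#>     159    1578     263

fisher_exact(matrix(c(10, 2, 317, 441), 2))$p
#> [1] 0.005723087
```

The gene calls are hairpins ranked by mean fold change: each listed gene had
all three of its shRNAs inside the top quartile of enriched hairpins, the
signature of a planted (or real) tumor-suppressor knockdown advantage. The
DE table shows the either-arm classification of the 2000 simulated genes,
and the Fisher p-value is the two-sided test of the reported
female-vs-male KDM5C mutation counts (10/327 vs 2/443), which prints as
0.006 at three decimals.

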