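---
title: "Methods: the KDM5C AML analysis pipeline and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the KDM5C AML analysis pipeline and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdm5caml)
```

## Scope

This package re-creates the downstream statistics of a tumor-suppressor
study built around the X-linked H3K4me2/3 demethylase KDM5C in acute
myeloid leukemia: a pooled in vivo shRNA screen identifies the gene, ChIP
and RNA sequencing of knockdown cells characterize the chromatin and
transcriptional consequences, mass spectrometry quantifies global histone
PTM shifts, and public patient cohorts supply survival and mutation
statistics. The deposited datasets themselves are out of scope; every stage
is instead exercised against a synthetic-data generator with planted ground
truth, so that each statistical claim can be verified as a recovery of a
known effect and each test's null behavior can be calibrated.

## Screen scoring

Hairpin counts are normalized to counts per million, a pseudocount of 0.5
is added after scaling (keeps log2 fold changes finite without distorting
high counts; configurable), and each hairpin's log2(output/input) is
averaged over output replicates *after* the log transform. Whether
replicates should be averaged before or after the log is genuinely open;
after-log averaging weighs replicates equally on the ratio scale and is the
package default.

The hit rule ranks hairpins by mean fold change *within the
direction-filtered set* (enrichment means log2 FC > 0; the percentile is
taken over enriched hairpins only, not the whole library) and qualifies the
top ⌊p/100 · n⌋ at p = 25. The floor is used because no interpolation rule
is specified anywhere for "top 25th percentile"; the floor is
integer-exact, conservative and trivially testable. "Multiple shRNAs" is
read as ≥ 2 and exposed as `min_multiple`. Ranking ties are broken by
hairpin id (lexicographic) so results are deterministic. Since filtering to
positive fold changes makes ranking by signed value and by magnitude
identical, the package ranks by magnitude within the filtered set.

An independent brute-force caller (explicit sort, slice, count) and a
closed-form hypergeometric null (probability that ≥ 2 of a gene's m ranked
hairpins land in the top K of N by chance) back the implementation in the
test suite.

## Chromatin states and differential regions

Signal is quantified as reads per kilobase of region per million mapped
reads (TPM). Mark presence replaces peak calling with a transparent rule:
present ⇔ replicate-mean TPM strictly above the `background_quantile`
(default 0.75) of that mark's region-wide distribution. The strictness
matters for degenerate inputs: a constant signal yields no presence calls.
Promoter states follow the standard two-mark partition (active / repressed
/ bivalent / unmarked).

For differential regions the published engine behind "differential peak"
volcano plots from duplicate ChIP-seq is typically unstated. A raw
two-sample t with two replicates per arm is unusable (2 degrees of
freedom, unstable variances), and ad hoc variance inflation (e.g. adding a
constant to every variance) makes null p-values strongly conservative and
fails calibration. The package therefore uses the field-standard
empirical-Bayes moderated t (limma) on log2(TPM + 0.5), which shrinks
per-region variances toward a common prior, gains degrees of freedom, and
keeps null p-values approximately uniform — verified by a 200-seed null
calibration in the test suite. The reported effect size stays the simple
log2 ratio of replicate-mean TPM with a 0.5 pseudocount (symmetric: an
all-zero region gets exactly 0), and FDR is the package's own
Benjamini–Hochberg implementation. The output records the engine in a
`method` attribute since it stands in for an unspecified published choice.

TSS metaprofiles average binned signal across regions with SEM = sd/√n per
bin; minus-strand regions are reversed so profiles read 5′→3′. Coordinates
are BED, 0-based half-open throughout; the TSS of a minus-strand interval
is `end − 1`.

## Differential expression and the class rule

The DE engine is intentionally simple and pluggable — the study-specific
contribution is the class logic, not the engine. Per arm: Welch t on
log2(CPM + 0.5), BH across genes, fold change as the log2 ratio of group
mean CPM after the pseudocount. CPM uses median-of-ratios effective library
sizes (geometric-mean reference) rather than raw totals: with hundreds of
genes deregulated in one direction, total-count normalization visibly drags
neutral genes into apparent change, and median-of-ratios scaling removes
that composition bias. All-zero genes are dropped and reported.

Classes follow the either-arm rule at FDR < 0.05: significant in at least
one arm, all significant arms concordant in sign. Arms significant in
opposite directions are classified neutral and flagged — the source
analyses are silent on this case, and the conservative choice preserves the
either-arm rule for concordant genes. Swapping the two arms leaves classes
unchanged (tested).

## Integration panels

Every stratified panel (signal change by DE class, occupancy by class or
state, fold change by promoter state, attributes such as CpG-island length
or enhancer counts by class) uses the same machinery: per-group n, median
and quartiles plus pairwise two-sided Mann–Whitney tests. Small groups
(< 2 values) are summarized but not tested. The rank test enumerates the
exact null when both groups are small (ties handled naturally) and
otherwise uses the tie-corrected normal approximation without continuity
correction, which keeps null p-values uniform at the group sizes the
pipeline produces. No correction is applied across panels — each
figure-panel analog is reported separately, matching the presentation style
it emulates — and an optional BH column exists where adjustment is
meaningful.

Genes map to one promoter (primary TSS = lowest start coordinate).
Enhancers map to the nearest TSS by midpoint distance with a 100 kb cap
and lower-coordinate tie-breaking; a brute-force all-pairs scan backs the
implementation. Stage profiles are class means over the five myeloid
differentiation stages (LSK, pre-GM, GMP, Gr, Mono), with the Spearman
correlation of the class-mean profile against the stage index; a perfectly
flat profile has undefined rank correlation and is reported as `NA`.

## PTM ratios

Relative abundances within a (variant, residue, condition, replicate)
group sum to 1. Ratios are of replicate means, p-values from two-tailed
t-tests, Welch by default (pooled available) — whether the original tests
pooled variances is unstated, and Welch is the safer default. P-values are
deliberately *unadjusted* by default, mirroring the stated analysis choice;
BH is opt-in. One consequence of closed compositions is worth noting: a
planted shift in one modification necessarily moves its within-residue
complement the opposite way after renormalization, so "only the planted
mark changes" can only hold approximately — the tests assert that the
planted H3K4me3 shift is the largest and most significant signal and that
the untouched residue (K27) stays null.

## Clinical statistics

Fisher's exact test, the Kaplan–Meier product-limit estimator, the
two-group log-rank test, BH and the Mann–Whitney test are implemented from
first principles in this package, because they *are* the analysis here;
`stats::fisher.test`, `survival::survfit`/`survdiff`, `stats::p.adjust` and
`stats::wilcox.test` serve as independent oracles in the tests instead of
as the implementation. Conventions, each of which is a deliberate choice
where the source is silent:

* Fisher two-sided p by the point-probability rule (sum of hypergeometric
  probabilities ≤ the observed one, with 1e-7 relative slack), the
  convention of common statistical software; odds ratio ad/bc with the
  degenerate bc = 0 case flagged.
* Median split: "High" strictly above the cohort median, ties go Low
  (reading "High (above median)" literally). The score is one gene or an
  unweighted sum (KDM5C + KDM5D for male patients, where the Y-linked
  paralog is redundant).
* Follow-up exclusion keeps records at exactly the boundary ("less than
  six months were excluded" ⇒ ≥ 6 months kept).
* The median split is computed before the exclusion by default (both
  orders available); the original order is unstated.
* Expression quartiles for mutation enrichment are rank-based with
  k = ⌊n/4⌋ per tail and deterministic tie handling by record order.

## The synthetic-data generator

The generator's defaults are the study conditions the package is tested
under; they are fixed once and not tuned per test.

* **Screen**: 849 hairpins over 315 genes (as evenly as possible, the
  remainder randomized by seed) plus 5% non-targeting controls; counts are
  negative binomial with variance μ + μ²·disp (Poisson at disp = 0),
  expected depth 1000 reads per hairpin, dispersion 0.05; 30 enriched and
  30 depleted genes planted at ±1.5 log2, applied to *all* of a gene's
  hairpins (matching the multi-shRNA hit logic); one input pool and three
  output replicates (the original replicate structure — mice pooled per
  comparison — is unstated, so it is a parameter, not a constant).
* **Epigenome**: one chromosome `chrS`, one 20 kb slot per gene, promoter
  = TSS ± 2 kb (no window sizes are stated anywhere, so a fixed convention
  keeps tests exact), enhancers 4–9 kb from their host TSS so each stays
  nearest to its host. State mixture: 10% bivalent, 12% active, 12%
  repressed, 66% unmarked — chosen so each mark's presence fraction (22%)
  sits below the default 0.75 background quantile, which makes the
  presence rule exact on noiseless data and is what lets the
  classification-recovers-planted-states invariant hold identically.
  KDM5C-high promoters (15% of all) are drawn from the bivalent and active
  classes, consistent with high occupancy at both active and bivalent
  low-activity promoters. Knockdown adds +1 log2 H3K4me3 and −1 log2
  H3K4me1 at KDM5C-bound regions. Replicate noise is multiplicative
  log-normal (0.25 log2 sd), which matches TPM-scale ChIP variability and
  preserves positivity.
* **Expression**: genes with bivalent KDM5C-high promoters gain +1.5 log2
  in both knockdown arms; active KDM5C-high promoters gain half that
  (+0.75) — the qualitative claim being modeled is that knockdown
  de-represses bivalent promoters more than active ones, and planting a
  weaker real effect at active promoters keeps that comparison
  well-defined rather than dependent on false positives. A planted-down
  set of 150 genes (modeling the indirect downregulation) is drawn from
  KDM5C-unbound promoters and additionally gets reduced occupancy (×0.3),
  shorter CpG islands (×0.5) and a 3× enhancer-assignment weight,
  mirroring the study's descriptive claims about downregulated genes.
  Counts are NB at mean depth 2000 with dispersion 0.01 over triplicates —
  low dispersion befitting transplanted clonal material, and the scale at
  which a 3-replicate Welch engine has the power the recovery tests need.
  Stage profiles decline (up genes) or rise (down genes) by 2 log2 units
  across the five stages with 0.1 sd noise.
* **Cohort**: 400 females and 400 males; below-median KDM5C hazard ratio 3
  in females, below-median KDM5C+KDM5D hazard ratio 2 in males; baseline
  hazard 0.03/month with exponential event and censoring (0.015/month)
  times; mutation columns at 8% baseline frequency with planted
  quartile-enrichment odds (8 for the top-quartile marker, 4 for the
  others) among females only.
* **PTM**: four K4 states and five K27 states per variant (H3.1, H3.3),
  four replicates, log-normal noise (σ = 0.1) renormalized to sum to 1;
  knockdown doubles the K4me3 base proportion.

All randomness flows from one root seed through named substreams (one per
artifact), so any single output is reproducible in isolation and identical
configurations produce byte-identical files (hash-tested).

What the generator does *not* emulate: read-level data (no FASTQ/BAM,
alignment or peak calling), multi-TSS genes, overlapping or nested
regulatory elements, correlated mark co-variation beyond the planted
states, batch effects, GC/mappability biases, competing risks or
non-proportional hazards, and mutation co-occurrence structure. Passing
tests therefore demonstrate that the statistics recover clean planted
effects at realistic noise — not that they are robust to every artifact of
real sequencing data.

## Numerical choices and degenerate inputs

* BH: own implementation (sort, scale, cumulative minimum), equal to
  `p.adjust(..., "BH")` to 1e-12 on random vectors; NA propagated.
* Exact Mann–Whitney: full enumeration when both groups ≤ 20 and the
  arrangement count ≤ 2e5; two-sided p compares |U − nm/2| with 1e-9
  slack.
* Zero-variance identical groups in any t-test are flagged (`p = NA`),
  never reported as p = 0.
* All-zero screen samples, unknown marks, unmapped output replicates,
  mismatched gene universes and malformed BED lines (reported with line
  number) raise informative errors.
* Problem sizes in the shipped tests: the default simulation (2000
  promoters, 500 enhancers, 849-hairpin screen, 800 patients) for recovery
  checks; 200-seed null calibrations at reduced sizes (60–100 regions or
  genes, 60 females) for uniformity of p-values; exhaustive Fisher
  enumeration over all 2×2 tables with total ≤ 60; a 10⁴-permutation
  log-rank reference on 40 patients. These sizes were chosen as the
  smallest at which the approximations under test are expected to hold.

## Known limitations

The DE engine is a transparent Welch-t/log-CPM pipeline, not a
dispersion-shrinkage NB model; at 3 replicates it under-calls weak effects
(visible in the confusion-matrix test as missed half-strength planted
genes). The differential-region engine is a stand-in for an unspecified
published method. Reported clinical quantities from the original cohorts
(DE gene counts, competitive enrichment factors, median survivals, patient
KM curves) depend on deposited data and are deliberately not reproduced;
the planted-truth and calibration suites take their place.
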