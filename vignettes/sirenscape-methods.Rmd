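---
title: "Methods: models, generator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the statistical models behind each pipeline
stage, the design of the synthetic-data generator, and the numerical
and software-design decisions — the material a reviewer would want
before trusting the results.

## 1. Coordinate conventions and the interval engine

All user-facing intervals are 0-based, half-open `[start, end)` — the
BED convention — carried in plain data frames with `chrom`, `start`,
`end` columns. Internally, operations convert to 1-based closed
`IRanges` (`start + 1`). Rather than reimplementing interval
arithmetic, the engine delegates to IRanges:

- `merge_intervals(x, max_gap)` is `IRanges::reduce()` with
  `min.gapwidth = max_gap + 1`, which reproduces mask semantics:
  abutting intervals merge at `max_gap = 0`, and gaps of at most
  `max_gap` bases close.
- `intersect_any` / `subtract_overlapping` use `overlapsAny()` with the
  ≥ 1 bp overlap rule of `bedops -e 1` / `-n 1`; the two results always
  partition the query.
- `count_per_bin` uses `countOverlaps()`; a feature straddling a bin
  boundary counts in every bin it touches, and the function refuses
  overlapping bins so counts are unambiguous.

Every operation is tested against independent oracles: a boolean
genome-mask implementation of merging, a quadratic all-pairs overlap
check, and a per-bin brute-force counter.

## 2. Cluster calling, core sets and the master list

`call_clusters` follows the island strategy of small-RNA cluster
callers: reads outside the dicer range (21–24 nt) are removed *before*
island formation, so degradation products cannot chain two islands;
remaining reads are dilated by `pad = 100` bp and merged; islands with
fewer than `mincov = 20` reads are dropped. Reported cluster
coordinates are the read-supported span (min start / max end of member
reads), not the padded span. The dominant read size is the modal
length, with ties broken toward the longer size so a 23/24 tie reports
24.

Per-tissue **core sets** (`core_clusters`) require support in all three
wild-type replicates: the replicate calls are pooled, merged at gap 0,
and each merged region is kept only if it overlaps a call from every
replicate. The **master list** (`master_clusters`) merges the core sets
across tissues at gap 0 and annotates each master cluster with the
contributing tissues. Both steps conserve covered bases relative to
their pooled input.

## 3. Quantification and wild-type-anchored normalization

`count_24nt` counts exactly the 24 nt reads overlapping each master
cluster by ≥ 1 bp. Because mutants in this pathway *globally* lose 24nt
siRNAs, median-of-ratios normalization across all samples would wrongly
inflate mutant signal. `wt_anchored_size_factors` therefore computes
median-of-ratios factors among the wild-type columns only, then maps
each non-wild-type sample onto that scale through sequencing depth:

```
anchor      = mean(wt_factor_i / wt_total_mapped_i)
mutant_sf   = anchor * mutant_total_mapped
```

so a mutant sequenced twice as deeply as the average wild type gets a
factor of 2 regardless of how little signal remains in its clusters.
The wild-type side is cross-checked against DESeq2's
`estimateSizeFactorsForMatrix` in the test suite; DESeq2 itself is not
a dependency.

## 4. The differential engine

`differential_clusters` fits, per cluster, a negative-binomial model on
normalized counts. The dispersion is estimated by method of moments on
the normalized scale — `Var(K/s) = mu * E[1/s] + alpha * mu^2` — pooled
across the replicated group(s) and floored at 0.01 to avoid degenerate
Wald statistics at small n. The test is a Wald test on the log2 fold
change with a delta-method standard error, followed by
Benjamini–Hochberg correction across testable clusters. Statuses:

- `reduced_DE`: log2FC ≤ −1 and FDR ≤ 0.01;
- `increased`: log2FC ≥ 1 and FDR ≤ 0.01;
- `unchanged`: everything else testable;
- `untestable`: zero counts throughout (a pseudocount keeps single-side
  zeros testable).

The study design includes single mutant libraries tested against
wild-type triplicates; in that 1-vs-3 case the dispersion comes from
the replicated side. Calibration (type-I error at the FDR threshold on
null NB data) and power (8-fold reductions at dispersion 0.05, mean
200) are asserted in the acceptance tests. The raw Wald p-values are
mildly anticonservative at n = 3 — a known property of plug-in
dispersion estimates — but the decision rule operates on the FDR
threshold, where calibration holds.

**Rescue rule.** DE at FDR 0.01 misses genuine partial reductions.
`rescue_reduced_clusters` promotes a cluster to `reduced_rescued` when
(i) its log2FC is below `log2(0.75)` ≈ −0.415 (a ≥ 25% reduction) and
(ii) it overlaps a hypo-CHH DMR that does not overlap any `reduced_DE`
cluster — independent methylation evidence standing in for statistical
significance. Rescue never removes a DE call.

## 5. DMR calling

`pairwise_dmrs` works on a fixed 100-bp grid anchored at coordinate 0,
making bins comparable across all comparisons. Per bin and context:

1. keep cytosine positions covered by ≥ 4 reads in *both* samples
   (joint-coverage filter, applied per site before pooling);
2. require ≥ 4 such cytosines in the bin;
3. pool methylated/total counts per sample and apply absolute
   methylation-difference thresholds — CG 0.40, CHG 0.20, CHH 0.10;
4. two-sided Fisher exact test on the pooled 2×2 table, BH-corrected
   across all candidate bins (those passing 1–2), call at FDR 0.01.

The Fisher p-value is computed vectorised from `dhyper` sums using the
same `1 + 1e-7` relative tolerance rule as `stats::fisher.test`, which
the tests verify to 1e-10. Direction is `hypo` when the first sample is
lower. `consensus_dmrs` intersects pairwise calls by bin, context and
direction — 3/3 for a mutant against wild-type triplicates, 9/9 for a
tissue contrast over 3×3 replicate pairings (`replicate_pairings`).
`combine_tissue_dmrs` unions per-pair consensus sets, annotating each
bin with its supporting pairs.

## 6. Landscape statistics

- `siren_loci` sorts clusters by descending wild-type-average fpkm
  (ties broken by id for determinism) and returns the shortest prefix
  whose cumulative share reaches the target (80%). A `1e-12` slack on
  the comparison guards against floating-point near-misses at exact
  targets.
- `classify_clusters` performs k-means under the 1 − Pearson distance
  by z-scoring rows first: for z-scored vectors, squared Euclidean
  distance is an affine function of 1 − r, so standard `stats::kmeans`
  optimises the intended criterion. Zero-variance rows (where r is
  undefined) go to a degenerate class 0; classes are relabelled by
  descending mean expression so labels are stable.
- `cv_comparison` uses the sample (n − 1) standard deviation over mean;
  zero-mean loci are excluded with a warning; distributions are
  compared by Welch's t-test.
- `arm_enrichment_permutation` assigns each cluster to arm or
  pericentromere by its midpoint, then compares the query's arm
  fraction against random same-size subsets of the master list. The
  add-one estimator `p = (1 + #extreme) / (1 + n_perm)` never returns
  zero; the most extreme possible result is `1 / (n_perm + 1)`.

## 7. The synthetic-data generator

The generator is not an afterthought: it is the instrument that makes
every stage falsifiable. `sim_config` fixes a complete experimental
design — tissues, cluster classes with per-tissue expression profiles,
genotype ablation maps (`clsy1` … `clsy1234`, `poliv`), and siren
structure — and `simulate_landscape` plants it on a genome.

Key design points:

- **Determinism by substreams.** Every sample's seed is derived as
  `substream_seed(seed, key)`, a 31-bit polynomial hash of a string key
  such as `"flower/WT/1/sirna"`. Adding samples never perturbs existing
  streams, and all derived seeds stay below 2^31. `with_seed` evaluates
  seeded code and then restores the caller's RNG state.
- **Siren share by construction.** The siren class's expected fpkm in
  the siren tissue is solved analytically so the planted set holds
  exactly the configured share (80%) of expected abundance — making
  exact recovery by `siren_loci` a sharp test rather than a tolerance
  check.
- **Reads.** Per-cluster 24nt counts are negative binomial (dispersion
  0.05) around expectations proportional to fpkm × width; minor 21–23nt
  classes are included at low frequency. Background reads are placed at
  a *sparse rate* (0.5 reads/kb) rather than as a fixed large fraction
  of the library: dense uniform background would chain islands across
  the 100 bp pad and corrupt cluster calling for reasons unrelated to
  the caller. The remainder of the library is carried in
  `total_mapped_reads` metadata so depth-based normalization still sees
  realistic totals.
- **Methylomes.** Cytosine positions are fixed per landscape at
  densities CG 0.04, CHG 0.04, CHH 0.25 per bp — CHH sites are by far
  the most frequent context in plant genomes, and this density gives
  100-bp bins ~25 CHH sites, so essentially every bin is a usable DMR
  candidate at 20× Poisson coverage. Methylation calls are binomial:
  CHH at 0.30 inside clusters active in the tissue (expected fpkm ≥ 2)
  and 0.02 elsewhere, dropping to baseline when the genotype ablates
  the cluster's class.
- **Truth accessors.** `expected_cluster_counts`,
  `genotype_effect_vector` and `planted_hypo_chh_bins` expose the
  planted truth. Planted DMR bins are defined as bins *fully contained*
  in an ablated active cluster: edge bins mix elevated and baseline
  signal by construction and are not recoverable in principle, so they
  are not part of the truth.

**Known limits.** Reads are placed uniformly within clusters (no
strand or positional structure); methylation contexts are independent
of the actual sequence; there is no mappability variation, no copy
number, and no partial ablation (effects are 0/1 multipliers). These
are deliberate: the generator targets the statistical contracts of the
pipeline, not sequence-level realism.

## 8. Problem sizes and runtime

The default design (2 chromosomes × 2 Mb, 596 clusters, 500k-read
libraries) exercises all stages at realistic per-base densities while
simulating in seconds. A compact design (1 chromosome × 1 Mb, 116
clusters, exactly 10^4 grid bins) is used where many replicates are
needed. The heaviest single call — a genome-scale pairwise CHH DMR
comparison — is vectorised end to end (rowsum aggregation keyed by bin,
vectorised `dhyper` sums) and runs in seconds; the full six-genotype
dependency analysis, including 18 pairwise DMR calls with shared
wild-type methylomes, completes in a few minutes on one core.
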