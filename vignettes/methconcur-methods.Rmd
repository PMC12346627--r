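---
title: "Read-level methylation concurrence analysis with methconcur"
author: "methconcur authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-level methylation concurrence analysis with methconcur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methconcur)
```

## The problem

Whole-genome bisulfite sequencing reports the methylation state of every
CpG covered by every read.  Most analyses immediately average these
observations into a per-region *methylation ratio*, discarding which states
co-occurred on the same DNA molecule.  Two regions with identical ratios
can be very different at the read level: one may contain a mixture of fully
methylated and fully unmethylated molecules (polarized epialleles), the
other a population of molecules each carrying a mosaic of both states.
Read-level metrics recover this molecular information.  `methconcur`
computes six of them per region, identifies regions where the read-level
pattern changes between sample groups *while the ratio does not*, extends
the concurrence statistic to single cells, and quantifies where the called
regions fall in the genome.

## Metrics

For a region, take every read clipped to the region's CpG columns, with
multiplicities as weights.  Let a read's pattern be its 0/1 state vector
over the covered CpGs.

* **Methylation ratio** — methylated observations / all observations.
* **MCR** (methylation concurrence ratio) — unmethylated observations
  residing on *partially methylated* reads (reads with both states),
  divided by all observations.  `MCR <= 1 - ratio` always; it is 0 when
  every molecule is fully polarized, regardless of the ratio.
* **MHL** (methylated haplotype load) —
  `sum_{l=1..L} l P(l) / sum_{l=1..L} l`, with `P(l)` the weighted
  fraction of length-`l` CpG substrings that are fully methylated, and `L`
  the longest clipped read (configurable cap).  Equals the ratio at
  `L = 1`.
* **MBS** (methylation block score) — per read,
  `sum_j l_j^2 / n^2` over its maximal runs of consecutive methylated
  CpGs (`n` = clipped length); averaged over reads.  Rewards contiguous
  methylation.
* **PDR** (proportion of discordant reads) — among reads covering at least
  4 CpGs (configurable), the weighted fraction carrying both states.
* **Entropy** — normalized Shannon entropy (bits per CpG) of the pooled
  4-CpG-window pattern frequencies; 1 when all 16 patterns are
  equiprobable.

Metrics that cannot be computed (no reads; no read spanning 4 CpGs) return
`NA`, never 0 — "no data" must not masquerade as "no heterogeneity".
Regions with total read multiplicity below `min_reads = 10` are flagged
low-coverage and left entirely `NA`.  Every metric is invariant to
replacing a count-`k` record by `k` duplicate records, which is what makes
pseudobulk aggregation exact (below).  All six implementations are tested
to `1e-12` against independent brute-force enumeration oracles on
thousands of random read sets.

## Formats and coordinates

Read haplotypes are exchanged as **MHAP** text records (chrom, 1-based
genomic positions of the first and last covered CpG cytosine, 0/1 pattern,
count, strand) or **PAT** records (chrom, 1-based per-chromosome CpG
ordinal, pattern over `C`/`T`/`.`, count).  Both are interpreted through a
`CpGIndex` built by scanning the forward strand of a reference for `CG`
(`build_cpg_index()`); the requirement that an MHAP pattern length equal
the number of indexed CpGs spanned doubles as a validation of the
coordinate dialect.  A `.` in a PAT pattern *splits* the read into
separate contiguous segments rather than being imputed: the metrics are
defined over observed CpGs only, and imputation would manufacture
concurrence evidence.  Reverse-strand reads are assumed destranded onto
the forward-strand CpG unit, the standard WGBS convention.  BED input and
output is 0-based half-open on disk and converted to 1-based inclusive
coordinates internally (via `rtracklayer`).

## Segmentation

`segment_blocks()` partitions a per-CpG ratio profile into homogeneous
blocks greedily: a CpG joins the current block if it lies within
`max_within_delta = 0.25` of the running block mean, is at most
`max_gap_bp = 500` downstream of the previous CpG, and does not push the
block's total ratio range beyond `2 * max_within_delta` (the range guard
prevents slow drift of the running mean).  Blocks with fewer than
`min_cpg = 4` CpGs are discarded.  This is deliberately a single-profile
homogeneity rule, not a multi-sample changepoint model; the rest of the
pipeline accepts any externally produced block BED, so the segmentation
module is interchangeable.

## Differential calling

Given per-sample metric tables assembled into region-by-sample matrices,
`call_differential()` applies, per region, two-sided Wilcoxon rank-sum
tests on the ratio and on the chosen pattern metric, and calls a region
when

* `p_ratio >= 0.05` and `|delta ratio| < 0.2` (the ratio is stable), and
* `p_metric < 0.05` and `|delta metric| > 0.2` (the pattern moves),

with deltas as absolute differences of group means over non-missing
samples.  Calls on MCR with direction *decreased* in the focal group are
MCDRs (methylation-concurrence-depleted regions).  Numerical choices: the
Wilcoxon p is exact for untied groups of at most 10, otherwise a normal
approximation with continuity and mid-rank tie correction; fully tied data
yields p = 1; no multiple-testing correction is applied to match the raw
`p < 0.05` + effect-size-gate procedure (BH correction can be applied
downstream to the returned p-values).  Two-sided tests and mean-based
deltas were chosen where the procedure leaves the variant open; both are
the most common reading.  Tissue specificity (`call_tissue_specific()`) is
a one-vs-rest comparison against all other groups pooled, requiring at
least two non-target groups.

A small-sample guard: with 3 vs 3 samples the smallest attainable exact
two-sided Wilcoxon p is `2/choose(6,3) = 0.1 > 0.05`, so no call is
possible at the default threshold; the caller emits a warning rather than
silently returning an empty set.  Five per group (minimum p
`2/252 ≈ 0.008`) is the practical floor for this design.

## Single-cell concurrence

`pseudobulk()` pools cell reads with multiplicities summed; because all
metrics are count-weighted this equals the bulk computation on the same
reads *exactly*, not approximately.  `sc_mcr()` evaluates, per cell and
per region of a fixed MCDR set, unmethylated observations on partial
clipped reads over all observations (reads must cover at least 2 in-region
CpGs — a single-CpG read can never be partial), then averages *across
regions with coverage*.  Pooling observations within a region before
averaging across regions keeps the statistic consistent with bulk MCR; a
per-read-average variant was considered and rejected for that reason.
Uncovered regions are excluded from the mean rather than imputed as 0,
since zero-imputation would bias shallow cells downward.
`read_category_profile()` reports the fully-unmethylated / partial /
fully-methylated read composition, the per-patient visualization of
concurrence loss.

## Enrichment

`annotate_regions()` assigns each region one category by the position of
its midpoint with a caller-supplied priority order (promoter before exon
before intron; promoter windows default to TSS −2000/+500 via
`promoters_from_tss()`).  `fisher_enrichment()` performs region-level
locus-overlap enrichment: the universe should be the ratio-stable
testable regions (all regions without a significant ratio difference), the
query a called subset, and the p-value is the one-sided upper
hypergeometric tail, with a Haldane 0.5 correction on the odds ratio for
degenerate tables.  Overlap is counted at region level (at least
`min_overlap_bp = 1` intersecting bases), matching the unit of analysis of
standard locus-overlap tools.

## The synthetic generator

`synth_config()` / `generate_bulk()` / `generate_cells()` emulate grouped
WGBS samples and sparse single cells with the methylation level and the
read-level concurrence controlled *independently*.  Each read of a region
with level `m` and polarization `pi` is, with probability `pi`, fully
methylated (probability `m`) or fully unmethylated (otherwise); with
probability `1 - pi` its CpGs are i.i.d. Bernoulli(`m`).  Under this
mixture `E[ratio] = m` for every `pi`, while the expected MCR of a span-`s`
read is `(1 - pi)((1 - m) - (1 - m)^s)`, strictly decreasing in `pi`.
Polarization is therefore a clean model of concurrence depletion at
constant level — the exact contrast the differential caller must detect.
It is a model of that contrast, not a claim about the data-generating
process of real tumors.

Default study conditions, chosen once from the biology:

* Null regions draw `m` from a bimodal mixture (70% Beta(6,2), 30%
  Beta(2,6)) mimicking the largely bimodal somatic methylome; background
  polarization is 0.1.
* Planted (concurrence-shifted) regions draw `m ~ U(0.3, 0.7)` and
  receive polarization 0.9 in the focal group.  Intermediate methylation
  is where concurrence shifts are attainable at all: `MCR <= 1 - ratio`
  caps the possible MCR difference at `1 - m`, so a 0.2 effect-size gate
  is out of reach above `m ≈ 0.7` for any polarization contrast.
* Regions are 8 CpGs (20 bp apart), reads span 4 CpGs placed uniformly,
  depth 50 per sample, 5 samples per group, 200 regions of which 25% are
  planted — the scale at which the recovery experiments below run in
  seconds.
* Single cells cover each region with probability 0.7 (dropout 0.3) with
  `1 + Poisson(2)` reads; the union of a group's cells is
  distributionally a bulk sample of the summed depth.

What the generator does **not** emulate: fragment-length and CpG-density
variation, non-uniform coverage, bisulfite conversion failure (a symmetric
per-CpG flip rate is available but off by default), strand asymmetries,
and any correlation structure between neighbouring regions.  Passing
recovery tests on this generator therefore demonstrates that the
*procedure* is correct and well-calibrated under its stated model, not
that real tumors meet the model's assumptions.

## The coefficient-of-variation panel

`cv_panel()` simulates six "tissues" that share every region's `m` and
differ only in polarization (grid 0 to 0.95), then ranks the five
read-level metrics by the median CV of their per-region group means.  One
subtlety deserves honesty: under the pure polarization mixture, the
expected group means of MCR *and* PDR are both exactly proportional to
`(1 - pi)`, so their deterministic CVs coincide, and the observed ranking
between them is decided by estimator dispersion.  In predominantly
methylated regions, unmethylated CpGs are rare and concentrated on
discordant reads, which makes the MCR estimator more dispersed than the
PDR estimator and lifts its CV above PDR's; at low methylation the
relation reverses.  The panel therefore emulates the predominantly
methylated fraction of the methylome (`m ~ Beta(8, 2)`) at modest depth
(20 reads per region, 3 samples per group, 300 regions), where MCR ranks
first consistently.  MHL, MBS (both riding on the large stable methylated
fraction) and entropy (bounded, sub-linear in `pi`) sit well below both.

## Problem sizes and determinism

The test suite and the acceptance script run the experiments at desk
scale: 19-point methylation grids at depth 500; 200-region two-group
recovery at depth 50 (5 vs 5); the 6-group CV panel above; 100 cells in
two populations; enrichment universes of about 200 regions.  Every
generator draw flows from a single integer seed (`with_seed` isolates the
package's RNG use from the caller's stream), and repeated runs of the
pipeline produce byte-identical output files, provenance headers
included (headers carry the package version, a config hash and input
checksums, deliberately no timestamps).

## Known limitations

* The segmentation is a single-profile greedy rule; joint multi-sample
  segmentation is out of scope.
* The differential caller has no paired-sample mode and no covariate
  adjustment.
* PAT per-chromosome CpG ordinals are a package convention; pipelines
  using genome-wide ordinals must re-index (the CpG BED export makes the
  mapping explicit).
* `sc_mcr` weights covered regions equally regardless of their read
  counts; deeply covered regions are not up-weighted.
* The enrichment universe is the raw region list as supplied; no disjoint
  re-tiling is performed.
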