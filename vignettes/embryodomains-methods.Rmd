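---
title: "Methods: broad-domain dynamics, stage specificity and allelic testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: broad-domain dynamics, stage specificity and allelic testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`embryodomains` packages the downstream analytics of a multi-stage embryo
H3K27ac study: before zygotic genome activation (ZGA), H3K27ac occupies
broad domains (tens of kb) coinciding with partially methylated domains
(PMDs); after ZGA the mark resolves into narrow peaks at enhancers and
promoters. This vignette explains each method, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where conventions were genuinely open.

## Coordinates and interval algebra

All coordinates are 0-based half-open (BED convention); refGene-style gene
tables are read in that convention directly. Interval merging uses the
inclusive rule `next_start − prev_end ≤ gap`, so peaks separated by exactly
5000 bp are merged by the 5-kb rule — this matches the behavior of the
common genomics toolkits. Merging, intersection and coverage are delegated
to GenomicRanges/IRanges behind the package's own function surface;
property tests compare them against per-base boolean-mask oracles on small
genomes, where agreement is exact.

## The enriched-domain caller

The caller is an explicitly simplified, self-contained local-Poisson
re-expression of broad-mode peak calling — not a bit-exact port of any
external caller. Given chip and input fragment-count tracks on `bin`-bp
bins (default 100 bp):

1. input counts are scaled by total chip/input depth;
2. each bin's background rate is
   `λ = max(genome-wide mean chip rate, scaled-input mean over each local window)`
   with local windows of 5 kb and 10 kb centered on the bin (edge windows
   use their truncated actual span);
3. each bin receives the upper-tail Poisson p-value `P(X ≥ c | λ)` of its
   chip count `c`;
4. *weak* bins (`p ≤ p_weak`, default 0.01) separated by at most `max_gap`
   bp (default 500) are linked into candidate domains;
5. candidates containing at least one *strong* bin (`p ≤ p_strong`,
   default 1e-3) are emitted.

The strong/weak two-threshold structure is what lets a single caller emit
both narrow peaks and broad domains: contiguous moderate enrichment is
held together by the weak threshold and the gap bridge, while the strong
seed guards against chains of marginal bins. Under chip ≡ input null
simulations the strong-bin rate stays below 2 × `p_strong` (the Poisson
tail is conservative at discrete counts), and planted 10–60-kb domains at
fold ≥ 4 are recovered with ≥ 80% reciprocal overlap.

All constants live in `caller_params()`. The narrow-enhancer preset used
for putative-enhancer calling is the same caller with a stricter
`p_strong`; there is deliberately no second implementation.

## Peak signal, filtering and cross-stage normalization

The *signal* of a peak is the sum of FPKM values of the 100-bp bins whose
midpoints fall in it; the *mean* over the same bins is its per-bin-scale
signal. FPKM normalizes each bin count by bin length in kb and library
size in millions; terminal partial bins use their actual length so edge
bins are not inflated. Fragments are assigned to bins by midpoint (floor
convention at boundaries), which conserves counts exactly.

Per stage, the peaks with the top 75% of signal are kept (nearest-rank
threshold, ties at the threshold kept) and survivors within 5 kb are
merged and re-scored — filter first, then merge; the pipeline encodes that
order.

Broadly distributed signal depresses per-bin FPKM, so stages are placed on
a common scale under the assumption that the most strongly modified
regions are fully modified at every stage: the factor for a stage is the
ratio of the *median* mean-signal of the top-25% peaks in the reference
stage to the same statistic in that stage ("median" is our reading of the
top-quartile center; `center = "mean"` is available). Applying the factor
equalizes the two medians exactly, by construction.

## PMDs and region methylation

PMDs are called on fixed 10-kb windows tiled from coordinate 0: a window
qualifies when its unweighted mean CpG methylation is `< 0.5` **and** it
has `> 20` covered CpGs (strict inequalities; a window with exactly 20
CpGs does not qualify); adjacent qualifying windows merge (gap 0). "Covered"
means per-CpG coverage ≥ 1 by default (`min_cov`); the threshold applies to
the unweighted window mean, not a coverage-weighted one — the simplest
reading, and the one implemented. Region methylation is likewise the
unweighted mean over CpGs in the region, flagged `NA` (never silently 0)
when the region contains no CpG. Lowering the methylation threshold can
only shrink the PMD set (tested as a monotonicity property).

## Entropy-based stage specificity

For a feature with signal `E_i ≥ 0` across `N ≥ 2` stages, relative signal
is `R_i = E_i / ΣE` and `H = −Σ R_i log2 R_i` bits, with `0·log2 0 ≡ 0`;
`H` ranges from 0 (one-hot) to `log2 N` (uniform). Features with
`H < 0.5` bits are stage-specific and assigned to their argmax-`R` stage.
All-zero features are flagged undefined and excluded, never scored 0
(which would wrongly mark dead features maximally specific). Gene-level
entropy uses raw FPKM, not log-transformed values, mirroring the enhancer
formula. In the pipeline, enhancer stage signal is the region-level
input-subtracted mean FPKM (subtract the enhancer's input FPKM, floor at
zero — the same convention as promoter signal); region-level subtraction
keeps the non-enriched-stage noise floor near zero, whereas flooring every
100-bp bin first would bias it upward.

## Enhancers, eRNAs, ZGA genes, differential features

*Putative enhancers* are distal (non-promoter) peaks with a DHS
overlapping them or within 500 bp of either edge. *eRNAs* are H3K27ac
peaks with no H3K4me3 overlap, not overlapping promoters or exons, with
RNA FPKM `> 0.5` at a stage (strict: exactly 0.5 does not qualify). *ZGA
genes* have post-ZGA FPKM `> 1` and pseudocounted fold change `> 3` over
the pre-ZGA stage. Fold changes throughout use a pseudocount of 0.1 FPKM
(configurable) to guard zero denominators; every reported fold states it.

`fold_change_differential()` has two modes. Fold-only classifies by the
pseudocounted ratio. Statistical mode — a deliberately simple,
self-contained count test — scales replicate columns to a common library
size, pools per condition, tests each feature's condition split with a
two-sided binomial test, adjusts by Benjamini–Hochberg, and requires both
the fold and the FDR cutoff (presets: fold > 2 with FDR < 0.05; fold > 3
fold-only). Under 5 000-feature null simulations it flags well under 10%
of the nominal FDR budget.

## Genomic annotation

Element sets are built gene-wise and unioned per class: promoter =
TSS ± 2.5 kb (strand-aware; the TSS of a minus-strand gene is its rightmost
coordinate), TES = TTS ± 2.5 kb, exons as annotated, intron = gene body
minus exons minus promoter/TES windows; windows are clipped at chromosome
edges rather than rejected. A peak is assigned to the highest-priority
class with which it overlaps ≥ 150 bp, priority promoter > TES > exon >
intron, else intergenic — exactly one label per peak. Distal peaks link to
all genes with TSS within 300 kb of the peak center; the closest-TSS gene
is reported with equidistant ties broken lexicographically by gene id, so
outputs are deterministic. Where one gene has several transcripts the
longest-transcript convention applies upstream; promoter marking offers
both the ≥ 1 bp and the 150-bp criterion because either reading is
defensible.

## Repeats and allelic testing

Repeat-family enrichment is the ratio of observed probability (peak bp
covering the family / total peak bp) to expected probability (family bp /
genome bp); under uniform random peak placement the mean ratio is 1 within
simulation tolerance. Family expression profiles count fragments by
midpoint over non-exonic elements — an element is excluded when ≥ 50% of
it lies in exons (the exclusion fraction is unstated in common practice;
0.5 is the package default and configurable) — normalized per million
library fragments and z-scored across stages; zero-variance families are
flagged and zeroed rather than producing NaN.

Allelic peaks require ≥ 10 SNP-informative reads per kb to be tested.
Tested peaks get a one-degree chi-square statistic of the maternal/paternal
split against the background maternal fraction ρ (estimated from the
dataset totals by default, overridable), without continuity correction
(Yates optional), BH-adjusted across tested peaks. A call is maternal when
adjusted p < 0.001 and maternal:paternal > 5 (paternal symmetric; a zero
denominator counts as infinite fold and qualifies). At ρ = 0.5 and depth
50 the fold filter dominates: 10 000 null peaks yield at most one call,
while planted 95:5 peaks with ≥ 30 reads are detected essentially always.

## The synthetic-data generator

`simulation_config()` fixes every condition once and derives all
randomness from a single seed through R's default Mersenne–Twister stream;
each operation scopes a stable sub-seed so outputs are identical
regardless of call order, across platforms.

Defaults describe a minute-scale but statistically stable toy study: a
10-Mb single chromosome and 1e6 single-interval fragments of 200 bp per
library (fragment pairing is not modeled — the analyses consume densities
only). Pre-ZGA stages share 40 planted broad domains of 10–60 kb at fold 5
(~14% of the genome, comparable to the reported pre-ZGA coverage scale);
post-ZGA stages carry 80 narrow 1–3-kb plants at fold 8, of which 25% are
exclusive to one post-ZGA stage (the ground-truth stage-specific
enhancers) and 30% per stage are transcribed (the ground-truth eRNAs).
Broad and narrow plants are placed jointly with ≥ 30-kb separation so that
no narrow plant sits inside a broad domain or its flanking PMD — otherwise
a "stage-specific" plant would also carry pre-ZGA signal and the planted
labels would be incoherent. PMD truth pads each broad plant by 25 kb
(PMDs of realistic 60–110 kb scale), unifying padded plants closer than
20 kb so distinct PMDs are always separated by at least two 10-kb windows
of fully methylated sequence and remain individually resolvable.

Methylomes place CpGs at 2 per 100 bp; per-CpG methylation is
Beta-distributed (concentration 10) with mean 0.35 inside PMDs and 0.85
outside — Beta because methylation levels are bounded in [0, 1] — and
coverage is Poisson with mean 15. RNA libraries concentrate their mass at
weight 5000 in exons and the stage's planted eRNA regions: on a 10-Mb toy
genome a uniform RNA background would put intergenic FPKM near 100 (FPKM
background depends only on genome size), swamping the 0.5 eRNA cutoff;
concentrating the mass reproduces the near-zero intergenic background of
real RNA-seq. Allelic counts are Poisson (mean 50) with binomial maternal
draws at ρ = 0.5 for null peaks and 0.95 toward a random parent for the
planted 5%. Expression matrices draw log-normal baselines; planted ZGA
genes are < 0.5 FPKM pre-ZGA and jump above both cutoffs; planted
stage-specific genes put 95% of their signal on one stage (H ≈ 0.39,
safely below the 0.5-bit threshold; a 90% share would sit at H ≈ 0.63 and
would not be recoverable by design).

What the generator does **not** emulate: real genome scale and chromosome
structure, sequence (no FASTA/FASTQ, no SNP phasing), mappability and GC
artifacts, replicate structure, fragment-length variation, copy-number
and duplication noise. Passing tests therefore demonstrate that the
implementations apply the stated rules correctly and recover planted
structure under controlled noise — not that the thresholds are optimal
for any particular real dataset.

## Problem sizes and runtime

Test and acceptance runs use the default 10-Mb/1e6-fragment scale: a full
four-stage pipeline run takes ~20 s on one CPU; caller calibration uses
ten null seeds; allelic calibration uses 10 000 null peaks; oracle
comparisons use 10-kb mask genomes with hundreds of random instances.
These sizes were chosen to keep Poisson statistics stable (≈10 expected
fragments per 100-bp background bin) while staying minute-scale.

## Known limitations

- The caller's λ maximizes over fixed local windows; it does not model
  fragment-length shift, duplication or summit refinement.
- The statistical differential mode is a pooled binomial count test — a
  stated stand-in for dispersion-aware negative-binomial frameworks; with
  few replicates and strong biological variability it will be
  anti-conservative relative to those.
- Venn/inheritance overlap defaults to ≥ 1 bp; a fraction-of-peak
  criterion is provided because published overlap counts rarely state
  their rule, and neither is asserted as canonical.
- Multi-chromosome genomes are supported throughout, but the default
  study conditions use one chromosome; planted-interval placement assigns
  chromosomes proportionally to length.
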