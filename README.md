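# embryodomains

Chromatin in early embryos is organized very differently before and after
zygotic genome activation (ZGA). Before ZGA, active histone marks such as
H3K27ac spread over broad domains tens of kilobases wide that coincide with
partially methylated domains (PMDs); after ZGA they collapse into narrow,
enhancer- and promoter-like peaks. `embryodomains` implements the
downstream analytical machinery needed to study that transition from
stage-series ChIP-seq, methylome, RNA and allelic count data, together with
a deterministic synthetic-data generator that plants all of those
structures with known ground truth so every analysis step is testable
without any sequencing download.

It is aimed at computational biologists analyzing (or simulating)
multi-stage embryo epigenomes: each analysis rule is exposed as a plain R
function over data.frames and binned tracks, and `run_pipeline()` sequences
them end to end.

## What it computes

- **Enriched-domain calling** — a self-contained local-Poisson
  re-expression of broad-mode peak calling: per 100-bp bin, the background
  rate is λ = max(genome-wide chip mean, scaled-input mean over 5-kb and
  10-kb local windows); bins are scored by the upper-tail Poisson p-value
  of their chip count; weak bins (p ≤ 0.01) separated by ≤ 500 bp are
  linked, and candidates containing a strong bin (p ≤ 1e-3) become peaks.
  Peaks are scored by the sum and mean of 100-bp-bin FPKM, the top 75% by
  signal are kept, survivors within 5 kb are merged, and lengths are
  classified as typical (≤ 10 kb) or broad (> 10 kb, > 20 kb, > 50 kb).
- **Cross-stage normalization** — assuming the most strongly modified
  regions are fully modified at every stage, the median mean-FPKM of the
  top-25% peaks is equalized between a reference stage and every other
  stage (`stage_scale_factor()`).
- **PMD detection** — 10-kb windows with mean CpG methylation < 0.5 and
  > 20 covered CpGs, merged (`call_pmds()`).
- **Stage specificity** — for signal E_i across N stages, R_i = E_i / ΣE
  and H = −Σ R_i log2 R_i; features with H < 0.5 bits are stage-specific
  and assigned to their argmax stage (`entropy_score()`,
  `select_stage_specific()`).
- **Regulatory definitions** — putative enhancers (distal peaks with a DHS
  within 500 bp), eRNAs (distal non-exonic H3K27ac peaks without H3K4me3
  and RNA FPKM > 0.5), ZGA genes (post-stage FPKM > 1 and fold > 3 over the
  pre-stage), fold-change/FDR differential features.
- **Genomic annotation** — peak assignment to promoter / TES / exon /
  intron / intergenic with a 150-bp minimum overlap and that priority
  order; distal peak-to-gene links within TSS ± 300 kb.
- **Repeats and alleles** — observed/expected length-ratio enrichment of
  peaks in transposon families; family × stage expression z-scores
  (exonic elements excluded); allele-specific peaks by chi-square against a
  background maternal fraction with Benjamini–Hochberg adjustment
  (adjusted p < 0.001 and allelic fold > 5 at ≥ 10 informative reads/kb).

## Worked example

```r
library(embryodomains)

cfg <- simulation_config(seed = 1)
cfg
#> simulation_config: seed 1, 10,000,000 bp genome, stages 2cell > 4cell > 8cell > morula (pre-ZGA: 2cell, 4cell)
#>   planted: 220 enrichment regions, 15 PMDs, 40 ZGA + 40 stage-specific genes

m <- run_pipeline(cfg, "run1")
m
#> run_manifest: seed 1, 4 stages (reference 8cell), 18.6 s
#>   2cell    peaks   30 | broad>10kb  30 | >50kb  7 | coverage  12.5% | scale 2.282
#>   4cell    peaks   30 | broad>10kb  30 | >50kb  7 | coverage  12.5% | scale 2.293
#>   8cell    peaks   65 | broad>10kb   0 | >50kb  0 | coverage   1.4% | scale 1.000
#>   morula   peaks   64 | broad>10kb   0 | >50kb  0 | coverage   1.4% | scale 0.994
#>   PMDs: 15 (broad-domain overlap 100.0%); enhancers: 62 (16 stage-specific)
#>   eRNAs: 19; ZGA genes: 82; allelic calls: 1 maternal / 2 paternal
```

Reading the manifest: the two pre-ZGA stages carry only broad domains
(including seven > 50 kb each) covering 12.5% of the toy genome, while the
post-ZGA stages carry only typical peaks covering ~1.4% — the planted
broad-to-narrow transition, recovered by calling alone. Broad stages get
scale factors ≈ 2.3 because spreading the same signal over wide domains
depresses per-bin FPKM. Every called broad domain lies in a called PMD, and
the 16 stage-specific enhancers are exactly the planted stage-exclusive
narrow peaks that survive the distal + DHS filters.

The entropy score behaves the same way on any feature × stage matrix:

```r
entropy_score(rbind(enhA = c(120, 2, 3, 1), enhB = c(40, 38, 41, 44)))
#>   feature         H stage
#> 1    enhA 0.3456787     1
#> 2    enhB 1.9979736     4
```

`enhA` concentrates its signal at stage 1 (H = 0.35 < 0.5 bits:
stage-specific); `enhB` is near-uniform (H ≈ log2 4 = 2: ubiquitous).

A thin command-line front end is installed with the package:

```sh
Rscript inst/exec/embryodomains run --seed 1 --outdir run1
```

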