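Package: embryodomains
Title: Broad Histone Domain Dynamics in Early Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analytical machinery for studying H3K27ac broad-domain
    dynamics across early embryonic stages: a simplified local-Poisson
    broad-domain caller with top-signal filtering, gap merging and length
    taxonomy; cross-stage signal normalization by top-quartile medians;
    partially methylated domain (PMD) detection from CpG tables;
    Shannon-entropy stage-specificity scoring for putative enhancers and
    genes; eRNA and zygotic genome activation (ZGA) gene definitions;
    transposable-element enrichment and expression statistics; and
    allele-specific peak testing. A deterministic synthetic-data generator
    plants broad-to-narrow domain transitions, PMDs, allelic biases and
    stage-specific expression so every stage of the pipeline is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
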