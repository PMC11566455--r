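Package: rdcnv
Title: Read-Depth Copy Number Variation Calling, CNVR Annotation and
    V(ST) Differentiation Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A windowed read-depth pipeline for copy number variation (CNV)
    discovery in multi-sample whole-genome sequencing cohorts. Computes
    per-window read depth from read placements, corrects GC bias by bin-median
    rescaling, normalizes each sample to a diploid baseline of 1.0, calls
    per-sample CNV segments with depth thresholds, merges calls across samples
    into CNV regions (CNVRs) using a gap-fraction plus depth-correlation rule,
    classifies CNVRs as deletion, duplication or mixed, annotates them against
    gene models and QTL intervals, computes the V(ST) population
    differentiation statistic per CNVR, and implements qPCR relative
    quantification (2 x 2^-ddCt) for validation. Ships a synthetic cohort
    generator that plants CNVs with known copy numbers so the whole pipeline is
    testable end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
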