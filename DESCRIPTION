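Package: methconcur
Title: Read-Level DNA Methylation Concurrence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes read-level DNA methylation pattern metrics
    (methylation ratio, methylation concurrence ratio, methylated
    haplotype load, methylation block score, proportion of discordant
    reads, and methylation entropy) from methylation haplotype files
    (MHAP and PAT formats), segments per-CpG methylation profiles into
    homogeneous blocks, calls regions whose read-level pattern changes
    between sample groups while the methylation ratio does not
    (methylation-concurrence-depleted regions, MCDRs), derives a
    single-cell concurrence statistic with pseudobulk aggregation, and
    quantifies genomic-feature annotation and one-sided Fisher overlap
    enrichment of called regions.  Includes a synthetic read-haplotype
    generator with independently controlled methylation level and
    concurrence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
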