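Package: hapmeth
Title: Haplotype-Aware Analysis of Whole-Genome Bisulfite Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for haplotype-resolved DNA methylation analysis of
    whole-genome bisulfite sequencing (WGBS) data in plants, motivated by
    5-azacytidine-induced epimutant populations. Implements binomial
    methylation calling against a lambda spike-in conversion control,
    weighted methylation levels, sliding-window differential methylation
    (DMR) detection with hyper/hypo classification, genomic-feature
    annotation and gene metaplots, expression-rank versus methylation
    intersection statistics, allele-specific expression and methylation
    calling between maternal and paternal haplotypes, and integration with
    SyRI-style structural variants. A synthetic-data module generates
    haplotype pairs, methylomes and allele count matrices with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
VignetteBuilder: knitr
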