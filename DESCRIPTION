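Package: methylshift
Title: Whole-Genome Bisulfite Methylome Analysis of Stress-Induced
    Methylation Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for prokaryotic whole-genome bisulfite
    sequencing (WGBS) methylomes across stress and recovery conditions.
    Calls 5mC sites from per-cytosine count tables with a binomial test
    against the bisulfite non-conversion rate estimated from an
    unmethylated spike-in control, applies coverage and
    Benjamini-Hochberg FDR filters, and computes conversion-corrected
    methylation levels. Detects differentially methylated regions with a
    sliding-window Fisher exact test, partitions multi-condition mC-site
    sets into Venn cells with transgenerational retention and regain
    statistics, summarises methylation by sequence context and genomic
    feature, performs hypergeometric pathway enrichment of DMR-related
    genes, and includes a fully seeded synthetic bisulfite-count
    generator with truth ledgers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
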