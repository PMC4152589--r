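Package: peakforge
Title: Post-Processing, Reproducibility and Annotation of ChIP-Seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment processing for ChIP-Seq experiments: mapping-quality
    and proper-pair filtering of single-end and paired-end alignments,
    PCR-duplicate marking and library-complexity estimation, extended-fragment
    coverage tracks (bedGraph and fixedStep Wig) with per-million
    normalization, fold-change filtering of broad enrichment domains,
    peak-set overlap comparison, peak-to-gene assignment, pseudoreplicate and
    irreproducible discovery rate (IDR) consistency bookkeeping, GREAT-style
    binomial gene-ontology enrichment over gene regulatory domains, and
    duplicate-distribution diagnostics that contrast punctate and broad
    binding profiles. A synthetic-data module generates SAM alignments, peak
    calls, gene models and ontology annotations with controlled statistical
    structure so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
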