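Package: peakscape
Title: Peak-Centric Integration of Transcription-Factor Binding with
    Chromatin State and Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing transcription-factor ChIP-seq
    binding sites against companion epigenomic and transcriptomic data:
    classification of peaks into promoter, intragenic and distal
    intergenic regions with nearest-promoter gene assignment;
    hypergeometric and permutation tests of colocalization between peak
    sets on a binned genome; RPKM signal quantification at peaks with
    peak-centered and scaled TSS-to-TES metagene profiles; calling of
    directly activated and repressed target genes by intersecting
    binding with differential expression; IUPAC consensus motif
    scanning; and a fully seeded synthetic-data generator that plants
    known region compositions, colocalization odds ratios, signal
    enrichments and direct targets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
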