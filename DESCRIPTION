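Package: dualguide
Title: Editing-Outcome Classification for Dual-Guide CRISPR Exon-Excision
    Long-Read Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted long-read amplicon analysis of dual-sgRNA
    CRISPR exon-excision experiments. Models the targeted locus (SaCas9 guide
    sites, expected deletion and inversion products), derives diagnostic
    junction k-mers, demultiplexes reads by internal 8-mer barcode pairs,
    applies mean-quality and length filters, and assigns every read to one of
    eight editing-outcome categories (unedited, productive exon excision,
    indels at either or both cut sites, exon inversion, AAV vector-backbone
    integration, unclassified) by edit-distance-tolerant k-mer matching with a
    fixed-precedence decision rule. Includes a seeded synthetic-read generator
    emulating CCS-style amplicon libraries, per-category amplicon-size QC
    reports, and qPCR absolute-quantification arithmetic (standard curves,
    percent exon-skipped transcripts, vector genomes per host genome, and
    Pfaffl efficiency-corrected ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
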