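Package: pluriqtl
Title: Integrative SNP and Copy-Number Association Analysis for
    Pluripotent Stem Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating genomic variation with multi-level
    expression in pluripotent stem cell lines. Implements a probe-level
    quality-control cascade for exon-array style data (antigenomic
    GC-dependent background thresholds, cross-hybridisation and SNP-overlap
    flags, small-probeset masking), SNP-side filters (genetic variation,
    call confidence, copy-number and mosaic-region exclusion), a weighted
    copy-number/expression association statistic with a permutation null and
    Benjamini-Hochberg correction, cis linking of SNPs to genes, transcripts
    and exons at four interval definitions with per-pair linear-regression
    scans, and allele-differential transcription-factor binding scores from
    position weight matrices. Ships a synthetic-data generator with planted
    effects so every stage can be validated against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
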