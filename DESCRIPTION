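Package: bchromr
Title: B-Chromosome Marker Development and Genotyping from Sequencing
    Coverage, Multiplex PCR and qPCR Gene Dose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects B-chromosome-enriched genomic blocks from comparative
    0B/1B/2B short-read coverage ratios, designs variant-anchored three-primer
    multiplex PCR assays that report B presence/absence, validates them by
    in-silico PCR, and genotypes B copy number from qPCR Ct tables by gene
    dose ratio (GDR = 2^-dCt) against an HPRT reference with known 0B/1B/2B
    calibration controls. Includes a seeded simulator of 0B/1B/2B cohorts
    (reference scaffolds, a B chromosome built from duplicated A-complement
    blocks carrying diagnostic variants, short reads, microdissection-style
    contigs, and triplicate Ct tables) so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
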