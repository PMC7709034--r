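Package: mitovalr
Title: Whole Mitochondrial Genome MPS Haplotyping, QC and Mixture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Threshold-based haplotype calling for short-amplicon whole
    mitochondrial genome massively parallel sequencing data against a
    circularized rCRS axis, with the quality-control and interpretation
    metrics used in forensic developmental validation: amplicon balance,
    strand bias, relative read depth of negative controls, replicate
    concordance with discordance classification, NUMT-associated variant
    flagging, and two-contributor mixture detection and deconvolution from
    allele frequencies at mixed variant sites. Includes seedable generators
    for synthetic amplicon pileups (depth, error, homopolymer indel, NUMT
    and negative-control models) used to exercise the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
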