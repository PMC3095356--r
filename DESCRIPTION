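Package: allelemine
Title: Allele Mining of Resistance-Gene Allelic Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing allelic series of plant disease
    resistance genes from germplasm screens. Implements the accession
    screening funnel (phenotype, haplotype marker, known-allele
    exclusion, candidate selection), consensus-relative variant calling
    on near-identical allele alignments, detection of polymorphic
    sequence blocks and attribution of their donors (gene-conversion
    footprints and chimeric alleles), and domain-partitioned nucleotide
    diversity and synonymous/non-synonymous substitution statistics.
    Includes a simulator that generates allelic series, diverged
    paralogs and accession panels with known ground truth so every
    pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
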