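Package: genomescan
Title: Genome Characterization of a Transformed Cell Line by Variant, LOH,
    Repeat-Indel, Copy-Number and Viral-Integration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for characterizing a resequenced genome
    against a reference: six-class strand-collapsed mutation spectra,
    unique/shared variant partitioning across samples, block-based scanning
    for copy-neutral loss of heterozygosity, classification of indels at
    tandem repeats with enrichment curves, Grantham-distance triage of
    coding mutations, read-depth chromosome copy-number estimation with
    B-allele-frequency state calls, and retroviral integration-site
    detection from mixed assembly scaffolds and chimeric read pairs.
    Includes a synthetic diploid-genome generator with planted truth so
    every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    vcfR,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
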