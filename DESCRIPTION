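Package: rootstock
Title: Alignment-Free SNV Detection and Super-Population Ancestry
    Inference from Genome Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reference-guided, alignment-free detection of single
    nucleotide variants from whole-genome sequencing reads or assemblies
    using a Bloom filter of canonical sample k-mers, followed by global
    and local super-population ancestry inference. Candidate variants are
    cross-referenced against an allele-frequency panel (1000 Genomes
    integrated-variant-call convention) and each of the five continental
    super-population labels is scored by the product of its mean allele
    frequency and its non-zero allele-frequency rate, genome-wide and in
    fixed-size genomic tiles. Includes a synthetic-data generator
    (Balding-Nichols differentiated panels, tile-mosaic admixed diploid
    donors, error-bearing reads) so the whole pipeline can be exercised
    and scored against planted truth, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
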