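Package: ampliphase
Title: Cross-Platform Concordance and Haplotype Analysis for Phased
    Amplicon Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Merges phased amplicon variant calls produced independently on
    an Oxford Nanopore (ONT) and an Illumina sequencing platform, classifies
    every (sample, site) pair into a four-state concordance category,
    restricts call sets to gene-model target windows (CDS, exons-plus,
    complete gene), filters by quality and read depth, tests each variant
    position for deviation from Hardy-Weinberg equilibrium and against
    external reference allele frequencies, assembles phased haplotypes from
    phase-set (PS) annotations, and tabulates cohort haplotype and diplotype
    frequencies.  A call-level synthetic cohort generator with configurable
    per-platform genotype-error, missed-call and phasing rates provides
    ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
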