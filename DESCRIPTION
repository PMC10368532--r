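Package: mosaicevo
Title: Genomic Characterization of Somatic-Mosaic CRISPR Tumor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize tumor evolution in somatic-mosaic CRISPR
    mouse models from tumor/normal sequencing summaries: sgRNA editing
    efficiency scored from cut-site pileups via log odds ratios, somatic
    variant filtering with murine and human (panel) threshold profiles,
    tandem-repeat indel screening, deduplicated 96-class trinucleotide
    mutation spectra, arm-level copy-number and aneuploidy profiling with
    whole-genome-doubling and B-allele-frequency summaries, and per-mouse
    sample progression trees built from shared-mutation distances with
    truncal/shared/private branch assignment. A synthetic cohort generator
    with known ground truth (clone tree, karyotype, purity, editing rate)
    makes every stage testable without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
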