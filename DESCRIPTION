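Package: breedsnp
Title: Breed-Specific SNP Discovery and Consensus Reference Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies population- (breed-) specific single nucleotide
    polymorphisms from per-breed multi-sample VCFs. Implements a site-level
    hard-filter cascade (multi-allelic removal, per-strand alternative read
    support, site and mapping quality, depth window with a median + 3 SD
    ceiling, duplicate-position removal, SNP/InDel proximity rules),
    within-breed fixation filters (missingness at most 7% and alternative
    allele frequency equal to one), the exclusive Venn partition of the
    per-breed fixed-SNP sets, breed-specific consensus reference FASTA
    construction, and a simplified coding-consequence classifier for SNVs
    against a GFF3 gene model. A seeded synthetic multi-breed cohort
    generator with a planted-variant truth table makes the full pipeline
    testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
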