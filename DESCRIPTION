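Package: cpgrates
Title: Context-Dependent CpG Mutation Rate Estimation from Polymorphism Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates sample-scaled germline mutation rates (muT) of
    unmethylated and methylated CpG sites per k-mer sequence context from
    site-level polymorphism presence/absence. Polymorphism probability is
    modelled as p = 1 - exp(-muT), a first-order correction for recurrent
    mutation saturation in large cohorts, with mutation rate linear in the
    site's germline methylation level and both intercept and slope varying by
    sequence context. Provides the genomic plumbing to assemble model-ready
    site tables from hard-masked FASTA, BED region masks, VCF polymorphism
    calls and bisulfite-sequencing methylation tables; a family of nested
    context models (4-mer, 6-mer, independent-flank and additive variants)
    fitted by exact maximum likelihood under the custom log(1-p) link;
    post-fit summaries including cross-model concordance, reverse-complement
    strand asymmetry tests and methylation-binned polymorphism rates; and a
    synthetic-data generator for calibration and end-to-end testing.
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
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
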