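Package: admixkit
Title: Cohort Genomics Toolkit for Admixed Whole-Genome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-implements the bespoke computational stages of a
    population-scale whole-genome sequencing cohort study of admixed
    individuals: two-step genotype quality flagging based on depth of
    coverage and allele balance, missingness filtering, and read-count
    based sex inference; filtering, merging, classification and landscape
    statistics for mobile element insertions (MEIs); construction and
    chromosomal anchoring of a non-reference DNA segment (NRS) library
    from contig alignments, coverage profiles and linked-read barcode
    evidence; Hardy-Weinberg incidence estimation for recessive disorders
    from curated pathogenic allele frequencies; and resampled HLA
    diversity statistics with novel-allele detection. A synthetic-cohort
    generator emits every input format the pipeline consumes, with
    planted ground truth, so the full pipeline is testable without access
    to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
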