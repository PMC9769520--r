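Package: tnseq5
Title: Tn5 Insertion Sequencing: Site Mapping, Gene Essentiality and
    Conditional Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled Tn5 transposon-insertion sequencing (Tn-Seq)
    libraries in bacteria. Converts transposon-genome junction reads into
    unique insertion sites with correction for the Tn5 9-bp target-site
    duplication and promoter orientation, computes library saturation and
    gap statistics, classifies genes as putatively essential under stringent
    rule-based criteria (non-hit, last-10%, 80%-gap), assesses clusters of
    consecutive essential genes by Monte-Carlo run-length permutation with
    Holm family-wise error control, and calls conditionally enriched or
    depleted mutants with a negative-binomial Wald test on median-of-ratios
    normalised count matrices. Includes a synthetic-data generator that
    simulates high-GC operon-structured genomes, transposon mutant pools,
    Wright-Fisher selection and junction reads with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
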