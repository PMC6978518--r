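Package: wgsage
Title: Somatic Mutation Burden, Subclonal Copy Number and Ageing
    Endophenotypes from Blood Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying age-related clonal and mitochondrial
    variation from standard-depth blood whole-genome sequencing, and for
    drift-aware cohort comparison of germline variation. Implements
    dynamic-threshold somatic single-nucleotide variant detection with
    per-locus sensitivity estimates, sensitivity-normalised 96-class
    mutational burden with non-negative matrix factorisation denoising,
    a negative-binomial phase-mixture model for subclonal aneuploidy with
    Kolmogorov-Smirnov segmentation and GC-bias correction, mitochondrial
    and Y-chromosome copy-number and heteroplasmy burden metrics, clonal
    haematopoiesis (CHIP) calling rules, genome accessibility tiering by
    depth bounds and morphological interval smoothing, Fisher carrier and
    direction-of-effect tests, polygenic-score comparison by a genetic-drift
    bootstrap, and permutation tests linking somatic burden to frailty
    measures. Seeded synthetic-data generators emulate every input so the
    full pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
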