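Package: radtrio
Title: De Novo Mutation Analysis in Mouse Trios Before and After Parental
    Irradiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for calling and characterising germline de novo mutations
    (DNMs) in parent-offspring trios, aimed at whole-genome comparisons of
    offspring conceived before and after parental exposure to ionizing
    radiation. Implements construction of the effective whole-genome coverage
    (EWC) region from per-base depth tracks, variant-allele-frequency based
    trio DNM filtering with parent-of-origin phasing from strain-informative
    polymorphisms, tandem-repeat and breakpoint-microhomology classification
    of small indels, clustering of multisite mutations, exact Poisson mutation
    rate estimation, linear parental-aging adjustment, and two-tailed
    Poisson-simulation tests for before/after count differences. A synthetic
    trio-cohort generator with known truth labels supports validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
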