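Package: scatdiet
Title: Faecal DNA Metabarcoding Diet Analysis for Vertebrate Predators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a faecal-DNA metabarcoding dietary
    analysis workflow for sympatric carnivores: simulation of tagged
    paired-end 12S V5 amplicon libraries with realistic artefacts (per-base
    error, tag jumps, blocking-oligo suppression of the host, contamination,
    negative controls), an OBITools-style read filter cascade (pair merging,
    alignment-score filtering, exact-tag demultiplexing, dereplication,
    length/abundance filtering, single-variant graph denoising), reference
    database construction by in-silico PCR, identity-based taxonomic
    assignment with lowest-common-ancestor logic refined by local species
    occurrence rules, per-sample contamination filters and 2 percent
    divergence collapse into discrete prey taxa, and dietary composition and
    niche statistics (frequency and proportion of occurrence, Levins'
    standardized niche breadth, Shannon diversity, Pielou evenness, Pianka
    overlap with a permutation test, Wilson score intervals, exact Wilcoxon
    signed-rank and Fisher r x c tests, seasonal and altitudinal
    stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'scatdiet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'assign.R'
    'denoise.R'
    'dietstats.R'
    'fixture.R'
    'pipeline.R'
    'reads.R'
    'simdata.R'
    'stats-exact.R'
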