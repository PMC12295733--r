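Package: eccProfiler
Title: Extrachromosomal Circular DNA Profiling, Annotation, and Clinical Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for tissue eccDNA (extrachromosomal circular
    DNA) profiling from split-read circle calls. Filters Circle-Map-style
    candidate tables with five read-support and coverage criteria, annotates
    accepted circles against functional and repetitive genomic elements
    (genes, enhancers, DNase I hypersensitive sites, CpG islands and shores,
    RepeatMasker classes) with an interval-overlap engine, builds a 58-feature
    per-sample quantification matrix normalized per million mapped reads, and
    runs tumor-versus-normal diagnostic modeling (five-classifier harness with
    cross-validated grid search and Shapley feature attribution) and
    disease-free-survival prognostic modeling (optimal-cutoff Kaplan-Meier,
    log-rank, univariate Cox). Ships a fully seeded synthetic-cohort generator
    so every stage is testable without access-controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    e1071,
    glmnet,
    class,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
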