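Package: codewise
Title: Coding-Potential Classification and Isoform Co-Expression Network
    Analysis for Plant Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated framework for characterizing transcript isoforms
    from developmental RNA-Seq experiments. Implements a weighted support
    vector machine classifier of transcript coding potential built on a
    twelve-slot feature vector (longest-ORF translation statistics, sequence
    content, conserved-domain counts and truncation, RNA secondary-structure
    minimum free energy, functional-annotation presence and an optional
    coding-potential score), together with isoform-level co-expression
    analysis: k-means clustering of temporal expression profiles into
    developmental super-clusters, a correlation-threshold co-expression
    network with degree-of-connectivity and hub detection, sense-antisense
    correlation screening, and pairwise domain categorization of splice
    variants. A synthetic-data module generates benchmark transcripts,
    feature tables and expression matrices with the class separations and
    temporal archetypes the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    e1071,
    igraph,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'transcript-io.R'
    'orf-translation.R'
    'folding.R'
    'feature-extraction.R'
    'codewise-classifier.R'
    'coexpression.R'
    'synthetic-data.R'
    'pipeline.R'
    'codewise-package.R'
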