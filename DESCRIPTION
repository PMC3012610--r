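Package: cypwaves
Title: Developmental Expression Waves of the Zebrafish Cytochrome P450
    Gene Complement
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the zebrafish cytochrome P450 (CYP) gene
    complement and its expression during early development. Provides a
    curated registry of the 94 zebrafish CYP genes with genomic
    coordinates and tandem-duplication cluster detection; a seeded
    simulator for single-color microarray time courses over the
    3-48 hours-post-fertilization embryo design with known ground truth;
    signal conditioning with rank-invariant piecewise-linear
    running-median normalization and probe quality filtering; an
    empirical-Bayes temporal differential-expression score for replicated
    time series alongside a per-probe ANOVA comparator; expression-wave
    clustering by hierarchically initialized K-means and the Cluster
    Affinity Search Technique; and absolute qPCR quantification from
    plasmid standard curves with reference-gene normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
biocViews: GeneExpression, Microarray, TimeCourse, Normalization,
    DifferentialExpression, Clustering, qPCR, Zebrafish
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
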