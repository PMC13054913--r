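Package: normsub
Title: Normative-Model Subtyping of Regional Gray Matter Volume with
    Transcriptomic and Receptor Contextualization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies data-driven patient subtypes from individualized
    deviations of regional gray matter volume (GMV) relative to a Gaussian
    process normative model fitted on healthy controls, after empirical-Bayes
    (ComBat) harmonization of multi-site data. Cluster existence is assessed
    with a SigClust test, subtypes are found by correlation-distance K-means
    with ensemble voting over cluster validity indices, and stability is
    quantified by subsample and leave-one-site-out adjusted Rand indices.
    Subtype abnormality maps (covariate-adjusted regional t-statistics) are
    related to neurotransmitter receptor/transporter density maps through
    multilinear models with permutation inference and dominance analysis, and
    to a correlated gene expression (CGE) connectome through neighbor-deviation
    coupling, Steiger Z comparison of dependent correlations, and
    rank-plus-permutation disease-epicenter mapping. A synthetic-cohort
    generator with known ground truth (site effects, covariate effects,
    opposite-pattern subtypes, modular expression, receptor mixtures, planted
    epicenters) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    mclust,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
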