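Package: otcc
Title: Unified Semi-Supervised Class Discovery and Prediction on
    Sample-Similarity Graphs
Version: 1.0.0
Authors@R:
    person("OTCC", "Developers", role = c("aut", "cre"),
           email = "otcc-dev@example.org")
Description: Casts both unsupervised class discovery and semi-supervised
    class prediction of disease subtypes (e.g. cancer subtypes from gene
    expression profiles) as one box-constrained quadratic labeling problem
    on a sample-similarity graph.  The convex objective is the Laplacian
    quadratic form of the similarity matrix; a customized fixed-point
    algorithm solves it at scale, an exact harmonic linear-system solver
    serves as verification oracle, and recursive divisive splitting with a
    minimum-similarity stopping rule handles multi-class discovery.
    Includes the microarray preprocessing recipe (clip/filter/log10),
    first- and second-order Pearson sample similarities, multi-class
    prediction strategies (class tree, one-vs-all, one-vs-one), synthetic
    benchmark generators (noisy block similarities, multi-component
    graphs), and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
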