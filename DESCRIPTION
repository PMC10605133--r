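Package: lipidflow
Title: Class-Level Lipidomics Profiling and Reaction-Activation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for semi-quantitative untargeted lipidomics of two-group
    tissue studies. Parses lipid shorthand nomenclature into classes and
    fatty-acyl building blocks, converts peak areas to protein-normalized
    concentrations via class-matched deuterated internal standards, and
    quantifies psychosine against a deuterated standard. Provides class-level
    group comparison tables, median normalization, Pareto/auto scaling, PCA
    with confidence ellipses, top-k differential heatmap clustering, a
    product/reactant reaction-activation statistic over lipid-class and
    fatty-acyl elongation/desaturation networks with enzyme and gene
    annotation, psychosine-class correlation, and a synthetic-data generator
    with planted ground truth for power and calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
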