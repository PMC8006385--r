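Package: mbkit
Title: Microbiome Count Data Analysis: Diversity, Differential Abundance
    and Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A scriptable toolkit for downstream analysis of microbial
    community profiles (16S rRNA OTU/ASV tables, shotgun metagenomic and
    metatranscriptomic count tables). Provides a coordinated container for
    counts, taxonomy and sample metadata built on SummarizedExperiment;
    import and export of tab-delimited tables, BIOM v1 files, PathoScope
    per-sample reports and a portable session archive; abundance transforms
    and taxonomy-level aggregation; feature and sample filtering with
    summary statistics; alpha diversity metrics with group tests; beta
    diversity distances with group-distance decomposition and PERMANOVA;
    PCA and PCoA; negative-binomial Wald and empirical-Bayes moderated-t
    differential abundance with extended per-group result columns;
    cross-validated biomarker selection with importance scores and ROC
    evaluation; and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    biomformat,
    jsonlite,
    yaml,
    MASS,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    vegan,
    limma,
    Rtsne,
    uwot
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
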