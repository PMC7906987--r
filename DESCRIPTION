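Package: metaCrosstalk
Title: Cross-Compartment Meta-Analysis of Kidney Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Dual-method differential-expression meta-analysis across
    case/control transcriptome cohorts (fixed-effect Hedges' g pooling and
    permutation-based SAM q-values with cross-dataset combination),
    tubule-versus-glomerulus DEG comparison, paired-sample cross-compartment
    correlation screening, secreted-protein annotation of correlated gene
    pairs, and a synthetic multi-cohort generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    metafor,
    optparse
biocViews: GeneExpression, DifferentialExpression, Microarray, Network
Config/testthat/edition: 3
RoxygenNote: 7.3.3
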