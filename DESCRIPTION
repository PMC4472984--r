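Package: ddCtScreen
Title: Relative Quantification and Candidate-Gene Prioritization for
    RT-qPCR Stress-Response Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline from raw RT-qPCR quantification-cycle (Cq)
    values to prioritized candidate genes for contrasting-genotype stress
    screens. Implements Livak 2^-ddCt relative quantification with replicate
    standard errors, fold-change plus one-tailed t-test responsiveness calls,
    cross-genotype expression contrasts computed on reference-normalized
    dCt values, tissue-overlap (Venn) partitioning with mixed-pattern
    exclusion, and a table-driven rule engine that classifies genes into
    overexpression (Group 1) and knock-down (Group 2) candidate classes.
    Includes a synthetic Cq generator with programmed ground truth so every
    stage is testable end to end, and a packaged qualitative call matrix for
    a 19-gene chickpea NAC transcription-factor dehydration screen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, qPCR, DifferentialExpression, Classification
RoxygenNote: 7.3.3
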