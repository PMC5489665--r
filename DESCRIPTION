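Package: stableRG
Title: Reference-Gene Discovery and Validation for qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for discovering and validating stable reference genes
    for qPCR normalization across developmental or experimental conditions.
    Screens genome-scale expression matrices for medium-expression,
    low-variability candidates; scores qPCR Ct data with three expression
    stability statistics (geNorm M-value with pairwise variation, the
    NormFinder model-based stability value, and the boxplot whisker D-value);
    applies consensus selection with mean-Ct and amplification-efficiency
    quality filters; determines the minimal reference-gene set from the
    geNorm V curve; and quantifies target genes by the 2^-ddCt method with
    multi-gene geometric-mean normalization factors. A synthetic-data module
    generates stage-structured expression matrices, Ct matrices with planted
    stable genes, dilution series, and trait series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
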