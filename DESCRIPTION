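Package: gerochem
Title: Hybrid Chemogenomic Modeling of Small-Molecule Regulation of Longevity Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A chemogenomic pipeline for predicting up- and downregulation of
    longevity-associated genes by small molecules across cell lines. From
    long-format perturbation Z-score tables it applies treatment-condition
    filters and per-cell-line left-right percentile labeling, builds gene
    ontology one-hot gene descriptors, Morgan circular-fingerprint drug
    descriptors, and cell-line descriptors from binary mutation markers plus
    FCBF-selected DNA-methylation beta values, trains a deep neural network
    alongside random forest, naive Bayes, and ridge logistic benchmarks, and
    ranks drugs for repurposing by counting desired drug-gene-cell
    interactions and scoring Cartesian prediction pools on normal cell lines.
    A seeded synthetic-world generator with planted drug-gene regulation
    signal makes the whole pipeline exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    igraph,
    ChemmineR,
    ChemmineOB,
    glmnet,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
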