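Package: cernaMod
Title: Discovery of miRNA-lncRNA-mRNA Regulatory Modules from Paired
    Tumor/Normal Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for competing endogenous RNA (ceRNA)
    regulatory-module discovery from paired case/control expression matrices of
    three RNA classes (mRNA, lncRNA, miRNA). Stages: TMM normalization and
    stability-selected differential expression (repeated 4/5 subsampling with
    intersection); construction of an mRNA interaction network under STRING-style
    confidence and co-expression filters; a fully connected neural classifier
    trained with Adam on binary cross-entropy, with per-feature Shapley-style
    attribution scores computed by backpropagated difference-from-reference
    multipliers; hub selection by Maximal Clique Centrality jointly with
    attribution scores; sign-constrained ceRNA triplet screening over validated
    miRNA target tables; and extraction of direction-consistent per-miRNA
    regulatory modules. Includes a seeded synthetic-data generator with planted
    differential expression, interaction graph and ceRNA triplets so the whole
    pipeline can be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    edgeR,
    igraph,
    jsonlite,
    yaml,
    class,
    e1071,
    rpart,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
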