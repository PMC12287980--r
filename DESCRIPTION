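Package: adrscore
Title: Drug-Side-Effect Relation Scoring from Biomedical Term Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts drug-side-effect relationships from term embedding
    similarity. Builds a binary drug-by-side-effect adjacency matrix from a
    relation table (SIDER-style TSV), computes within-axis pairwise similarity
    matrices under five metrics (cosine, negated Euclidean and Manhattan,
    generalized Jaccard, dot product), and scores every drug-side-effect pair
    by the product of two leave-one-out maximum similarities: the query drug's
    closest known drug for the side effect, and the query side effect's closest
    known side effect for the drug. Ranking quality is evaluated with a single
    ROC curve, tie-corrected AUC and a Youden-optimal threshold; predictions
    are validated against an external relation extract (FAERS-style TSV) with
    a balanced-resampling Fisher exact test and Haldane-Anscombe corrected
    odds ratios. A planted-factor synthetic benchmark generates relation
    structure, noisy factor-centroid embeddings and enriched external extracts
    so the full pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
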