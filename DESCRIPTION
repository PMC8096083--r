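Package: meshwalk
Title: Multi-Source Term Embeddings and Link Prediction for Biomedical Term Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Learns embeddings of controlled-vocabulary terms (such as MeSH
    headings) by fusing three heterogeneous data sources: a document corpus in
    which each document is a set of terms, an ontology directed acyclic graph,
    and a semantic-predication graph. Graphs are converted into term sequences
    with second-order (p,q)-biased random walks, the corpus is converted by
    uniform permutation sampling, the per-source sequence sets are equalized by
    up-sampling with replacement and merged, and a skip-gram model with uniform
    negative sampling is trained on the merged sequences. Embedding quality is
    evaluated by edge prediction on the predication graph using a
    connectivity-preserving 50/25/25 split with balanced negative sampling, a
    two-hidden-layer feed-forward classifier with early stopping, six ranking
    and classification metrics, classical link-prediction heuristics as
    baselines, and repeated-run significance testing. A synthetic fixture
    generator (planted-partition predication graph, random DAG ontology,
    block-structured corpus) makes the full pipeline testable at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
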