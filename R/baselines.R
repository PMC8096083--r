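#' Classical link-prediction heuristics
#'
#' Neighborhood-based scores computed on a graph (by protocol, the
#' train-positive graph, so the heuristics never see validation or test
#' edges):
#' \describe{
#'   \item{common_neighbors}{`|G(u) n G(v)|`}
#'   \item{jaccard}{`|G(u) n G(v)| / |G(u) u G(v)|` (0 when both
#'     neighborhoods are empty)}
#'   \item{preferential_attachment}{`|G(u)| * |G(v)|`}
#'   \item{adamic_adar}{`sum over z in G(u) n G(v) of 1 / ln |G(z)|`;
#'     common neighbors of degree <= 1 are skipped to avoid dividing by
#'     `ln 1 = 0` (degree-1 common neighbors cannot occur in a simple graph
#'     anyway, but degenerate inputs are guarded)}
#' }
#'
#' @param graph a [term_graph()]
#' @param u,v term tokens (equal-length character vectors of pair endpoints)
#' @param method one of `"jaccard"`, `"preferential_attachment"`,
#'   `"adamic_adar"`, `"common_neighbors"`
#' @return numeric score vector, one per pair
#' @export
heuristic_score <- function(graph, u, v,
                            method = c("jaccard", "preferential_attachment",
                                       "adamic_adar", "common_neighbors")) {
  method <- match.arg(method)
  iu <- match(u, graph$nodes)
  iv <- match(v, graph$nodes)
  if (anyNA(iu) || anyNA(iv)) stop("pair endpoint not in graph")
  deg <- lengths(graph$adj)
  vapply(seq_along(iu), function(i) {
    nu <- graph$adj[[iu[i]]]
    nv <- graph$adj[[iv[i]]]
    switch(method,
      common_neighbors = length(intersect(nu, nv)),
      jaccard = {
        un <- length(union(nu, nv))
        if (un == 0L) 0 else length(intersect(nu, nv)) / un
      },
      preferential_attachment = length(nu) * length(nv),
      adamic_adar = {
        z <- intersect(nu, nv)
        z <- z[deg[z] > 1L]
        if (length(z) == 0L) 0 else sum(1 / log(deg[z]))
      })
  }, numeric(1))
}

#' Evaluate a heuristic on an edge split
#'
#' Scores the test positives and negatives on the train-positive graph and
#' produces the same [metrics_report()] as the embedding pipeline. The
#' ranking metrics (MAP, AUROC, AUPRC) are threshold-free; for P/R/F1 the
#' decision threshold is the median test score (a documented convention,
#' since heuristics output unbounded scores rather than probabilities).
#'
#' @param train_graph [term_graph()] built from the training positives (node
#'   set should cover all split endpoints)
#' @param split an [make_edge_split()] result
#' @param method heuristic name (see [heuristic_score()])
#' @param average P/R/F1 averaging convention
#' @return a [metrics_report()]
#' @export
evaluate_heuristic <- function(train_graph, split,
                               method = c("jaccard", "preferential_attachment",
                                          "adamic_adar", "common_neighbors"),
                               average = c("macro", "micro")) {
  method <- match.arg(method)
  pairs <- rbind(split$pos$test, split$neg$test)
  labels <- c(rep(1L, nrow(split$pos$test)), rep(0L, nrow(split$neg$test)))
  scores <- heuristic_score(train_graph, pairs[, 1L], pairs[, 2L], method)
  metrics_report(scores, labels, threshold = stats::median(scores),
                 average = match.arg(average))
}

#' Average per-source embedding tables into one
#'
#' The merged-embedding baseline: each term's vector is the mean of its
#' vectors across the tables that contain it (terms present in only some
#' sources are averaged over those sources). All tables must share the same
#' dimension.
#'
#' @param tables list of [embedding_table()] objects
#' @return an [embedding_table()] over the union of the terms
#' @export
average_merge_embeddings <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  d <- unique(vapply(tables, ncol, 0L))
  if (length(d) != 1L) stop("embedding dimension mismatch across tables")
  terms <- unique(unlist(lapply(tables, rownames)))
  acc <- matrix(0, length(terms), d, dimnames = list(terms, NULL))
  cnt <- numeric(length(terms))
  for (tb in tables) {
    idx <- match(rownames(tb), terms)
    acc[idx, ] <- acc[idx, ] + tb
    cnt[idx] <- cnt[idx] + 1
  }
  embedding_table(acc / cnt)
}
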