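#' Planted-partition predication graph
#'
#' Generates an undirected graph over `n` terms divided into `blocks` groups
#' (equal sizes, remainder in the last block): each within-block pair becomes
#' an edge with probability `p_in`, each between-block pair with `p_out`.
#' Stands in for a semantic-predication graph with community structure; the
#' block labels are retained on the result for diagnostics.
#'
#' @param n number of nodes
#' @param blocks number of planted blocks
#' @param p_in within-block edge probability
#' @param p_out between-block edge probability; `0 <= p_out <= p_in <= 1`
#' @param seed integer seed
#' @return a [term_graph()] with a `blocks` element (named integer vector)
#' @export
make_planted_graph <- function(n, blocks = 2L, p_in = 0.3, p_out = 0.02,
                               seed = 1L) {
  stopifnot(n >= 2, blocks >= 1, blocks <= n)
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  nodes <- sprintf("t%03d", seq_len(n))
  size <- n %/% blocks
  lab <- rep(seq_len(blocks), times = c(rep(size, blocks - 1L),
                                        n - size * (blocks - 1L)))
  names(lab) <- nodes
  with_rng_seed(seed, {
    cmb <- utils::combn(n, 2L)
    same <- lab[cmb[1L, ]] == lab[cmb[2L, ]]
    prob <- ifelse(same, p_in, p_out)
    keep <- stats::runif(ncol(cmb)) < prob
    edges <- cbind(nodes[cmb[1L, keep]], nodes[cmb[2L, keep]])
  })
  term_graph(edges, nodes = nodes, blocks = lab)
}

#' Random rooted DAG ontology
#'
#' Generates a random rooted tree (node `i` attaches to a uniformly chosen
#' predecessor) plus extra forward edges up to a mean of `branching` directed
#' edges per non-root node, so the directed export is acyclic and the
#' undirected walk view is connected. When `blocks` is given, the tree parent
#' is drawn from the same block with probability `block_bias` (when such a
#' predecessor exists), letting the ontology echo a planted partition.
#'
#' @param n number of nodes (>= 2)
#' @param branching target mean number of directed (child -> parent) edges
#'   per non-root node; 1 gives exactly a tree
#' @param blocks optional named block-label vector (as from
#'   [make_planted_graph()]); names must be the node tokens used here
#' @param block_bias probability of picking a same-block parent when one
#'   exists
#' @param seed integer seed
#' @return a [term_graph()] whose `directed_edges` hold the child -> parent
#'   orientation
#' @export
make_random_dag <- function(n, branching = 1.2, blocks = NULL,
                            block_bias = 0.8, seed = 1L) {
  stopifnot(n >= 2, branching >= 1)
  nodes <- if (!is.null(blocks)) names(blocks) else sprintf("t%03d", seq_len(n))
  stopifnot(length(nodes) == n)
  with_rng_seed(seed, {
    parent <- integer(n)
    for (i in 2:n) {
      cand <- seq_len(i - 1L)
      if (!is.null(blocks)) {
        same <- cand[blocks[cand] == blocks[i]]
        if (length(same) > 0L && stats::runif(1) < block_bias) cand <- same
      }
      parent[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    edges <- cbind(child = nodes[2:n], parent = nodes[parent[2:n]])
    n_extra <- max(0L, round(branching * (n - 1L)) - (n - 1L))
    if (n_extra > 0L) {
      cmb <- utils::combn(n, 2L)  # col = (j < i): candidate edge i -> j
      key <- paste(cmb[1L, ], cmb[2L, ])
      used <- paste(pmin(parent[2:n], 2:n), pmax(parent[2:n], 2:n))
      free <- which(!(key %in% used))
      pick <- free[sample.int(length(free), min(n_extra, length(free)))]
      extra <- cbind(child = nodes[cmb[2L, pick]], parent = nodes[cmb[1L, pick]])
      edges <- rbind(edges, extra)
    }
  })
  term_graph(edges, nodes = nodes, directed_edges = edges,
             blocks = blocks)
}

#' Block-structured synthetic corpus
#'
#' Each document draws a home block uniformly at random and a size uniform in
#' `doc_size_range`; each of its terms comes from the home block with
#' probability `purity` and otherwise uniformly from the rest of the
#' vocabulary. Terms within a document are sampled without replacement, so
#' every document is a set of at least two distinct terms.
#'
#' @param block_labels named integer vector mapping term tokens to blocks
#' @param n_docs number of documents
#' @param doc_size_range integer range `(min, max)` of document sizes, min >= 2
#' @param purity probability that a term comes from the home block, in \[0, 1\]
#' @param seed integer seed
#' @return a [term_corpus()]
#' @export
make_synthetic_corpus <- function(block_labels, n_docs = 2000L,
                                  doc_size_range = c(3L, 8L), purity = 0.9,
                                  seed = 1L) {
  stopifnot(purity >= 0, purity <= 1, n_docs >= 1,
            length(doc_size_range) == 2L, doc_size_range[1L] >= 2L,
            doc_size_range[1L] <= doc_size_range[2L])
  vocab <- names(block_labels)
  if (length(vocab) < doc_size_range[2L]) {
    stop("vocabulary smaller than the maximum document size")
  }
  block_ids <- unique(block_labels)
  by_block <- split(vocab, block_labels)
  with_rng_seed(seed, {
    docs <- vector("list", n_docs)
    for (i in seq_len(n_docs)) {
      size <- sample(seq(doc_size_range[1L], doc_size_range[2L]), 1L)
      home <- as.character(block_ids[sample.int(length(block_ids), 1L)])
      pool_home <- by_block[[home]]
      pool_out <- setdiff(vocab, pool_home)
      k_home <- stats::rbinom(1L, size, purity)
      k_home <- min(k_home, length(pool_home))
      k_out <- min(size - k_home, length(pool_out))
      if (k_home + k_out < 2L) k_home <- min(2L - k_out, length(pool_home))
      docs[[i]] <- c(
        if (k_home > 0L) pool_home[sample.int(length(pool_home), k_home)],
        if (k_out > 0L) pool_out[sample.int(length(pool_out), k_out)]
      )
    }
    term_corpus(docs)
  })
}

#' Full synthetic fixture
#'
#' Bundles the three data sources over one shared vocabulary: a
#' planted-partition predication graph (the prediction target and carrier of
#' the planted signal), a random DAG ontology whose tree structure leans
#' toward the same blocks, and a corpus whose documents preferentially
#' co-mention same-block terms. Defaults are the desk-scale study conditions
#' used throughout the package's end-to-end tests.
#'
#' @inheritParams make_planted_graph
#' @inheritParams make_synthetic_corpus
#' @param branching mean directed edges per non-root ontology node
#' @return list with elements `predications`, `ontology` ([term_graph()]s),
#'   `corpus` ([term_corpus()]), and `blocks`
#' @export
make_fixture <- function(n = 60L, blocks = 2L, p_in = 0.3, p_out = 0.02,
                         n_docs = 2000L, doc_size_range = c(3L, 8L),
                         purity = 0.9, branching = 1.2, seed = 1L) {
  pred <- make_planted_graph(n, blocks, p_in, p_out,
                             seed = derive_seed(seed, 21L))
  onto <- make_random_dag(n, branching = branching, blocks = pred$blocks,
                          seed = derive_seed(seed, 22L))
  corp <- make_synthetic_corpus(pred$blocks, n_docs = n_docs,
                                doc_size_range = doc_size_range,
                                purity = purity,
                                seed = derive_seed(seed, 23L))
  list(predications = pred, ontology = onto, corpus = corp,
       blocks = pred$blocks)
}
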