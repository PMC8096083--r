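# Shared fixtures and independent brute-force oracles used across the suite.
# Oracles are deliberately written with naive set/loop logic, independent of
# the package internals they check.

# random simple undirected term_graph on n nodes with edge probability p
rand_graph <- function(n, p, seed, nodes = sprintf("n%02d", seq_len(n))) {
  set.seed(seed)
  cmb <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(cmb)) < p
  term_graph(cbind(nodes[cmb[1L, keep]], nodes[cmb[2L, keep]]), nodes = nodes)
}

# neighbor set of a node from the raw edge matrix (no package adjacency)
bf_neighbors <- function(edges, node) {
  unique(c(edges[edges[, 1L] == node, 2L], edges[edges[, 2L] == node, 1L]))
}

# brute-force second-order transition law: classify each neighbor x of curr
# by BFS hop distance from prev (0 = prev itself, 1 = adjacent to prev,
# 2 = otherwise), weight 1/p, 1, 1/q, then normalize
bf_transition <- function(graph, prev, curr, p, q) {
  edges <- graph$edges
  nb_curr <- sort(bf_neighbors(edges, curr))
  nb_prev <- bf_neighbors(edges, prev)
  w <- vapply(nb_curr, function(x) {
    if (x == prev) 1 / p else if (x %in% nb_prev) 1 else 1 / q
  }, numeric(1))
  w / sum(w)
}

# brute-force bridges: remove each edge in turn and recount components
bf_bridges <- function(graph) {
  ig <- as_igraph(graph)
  base <- igraph::count_components(ig)
  keep <- vapply(seq_len(n_edges(graph)), function(e) {
    igraph::count_components(igraph::delete_edges(ig, e)) > base
  }, logical(1))
  graph$edges[keep, , drop = FALSE]
}

# brute-force rank metrics by explicit pair counting / threshold sweeps
bf_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

bf_average_precision <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  ap <- c()
  for (k in seq_along(y)) {
    if (y[k] == 1) ap <- c(ap, sum(y[1:k]) / k)
  }
  mean(ap)
}

bf_auprc <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  n_pos <- sum(y)
  prec <- rec <- numeric(length(y))
  for (k in seq_along(y)) {
    prec[k] <- sum(y[1:k]) / k
    rec[k] <- sum(y[1:k]) / n_pos
  }
  rec <- c(0, rec); prec <- c(prec[1], prec)
  area <- 0
  for (k in 2:length(rec)) {
    area <- area + (rec[k] - rec[k - 1]) * (prec[k] + prec[k - 1]) / 2
  }
  area
}

bf_macro_prf <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  vals <- sapply(c(0, 1), function(cls) {
    tp <- sum(pred == cls & labels == cls)
    p <- if (sum(pred == cls) > 0) tp / sum(pred == cls) else 0
    r <- if (sum(labels == cls) > 0) tp / sum(labels == cls) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  })
  rowMeans(vals)
}

# brute-force link-prediction heuristics from raw neighbor sets
bf_heuristic <- function(graph, u, v, method) {
  edges <- graph$edges
  nu <- bf_neighbors(edges, u)
  nv <- bf_neighbors(edges, v)
  cn <- intersect(nu, nv)
  switch(method,
    common_neighbors = length(cn),
    jaccard = if (length(union(nu, nv)) == 0) 0 else
      length(cn) / length(union(nu, nv)),
    preferential_attachment = length(nu) * length(nv),
    adamic_adar = {
      s <- 0
      for (z in cn) {
        dz <- length(bf_neighbors(edges, z))
        if (dz > 1) s <- s + 1 / log(dz)
      }
      s
    })
}

# tiny two-cluster corpus: terms within a cluster always co-occur, never across
two_cluster_sequences <- function(n_docs = 100, seed = 1) {
  set.seed(seed)
  seqs <- c(
    replicate(n_docs, sample(paste0("a", 1:5)), simplify = FALSE),
    replicate(n_docs, sample(paste0("b", 1:5)), simplify = FALSE)
  )
  sequence_set(seqs[sample(length(seqs))])
}

random_embedding <- function(terms, d, seed, sd = 0.01) {
  set.seed(seed)
  embedding_table(matrix(stats::rnorm(length(terms) * d, sd = sd),
                         length(terms), d,
                         dimnames = list(terms, NULL)))
}
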