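#' Walk parameters
#'
#' Parameters of the second-order biased random walk used to turn a term
#' graph into term sequences. `p` (return parameter) controls the tendency to
#' backtrack, `q` (in-out parameter) the tendency to move outward: the
#' unnormalized weight of stepping from the current node `v` to neighbor `x`,
#' given the previous node `t`, is `1/p` if `x == t` (hop distance 0), `1` if
#' `x` is adjacent to `t` (distance 1), and `1/q` otherwise (distance 2). The
#' defaults (p = 0.25, q = 4, r = 80 walks per term, length l = 10) are the
#' fixed settings used throughout the original study.
#'
#' @param p return parameter, > 0
#' @param q in-out parameter, > 0
#' @param r walks started per node, >= 1
#' @param l walk length in nodes, >= 1
#' @param seed integer seed making the generated sequence set reproducible
#' @return a `walk_params` list
#' @export
walk_params <- function(p = 0.25, q = 4, r = 80, l = 10, seed = 1L) {
  stopifnot(p > 0, q > 0, r >= 1, l >= 1)
  structure(list(p = p, q = q, r = as.integer(r), l = as.integer(l),
                 seed = as.integer(seed)),
            class = "walk_params")
}

#' Second-order transition distribution
#'
#' Distribution of the next node for a walk that moved `prev -> curr`, with
#' all edge weights equal to 1: each neighbor `x` of `curr` receives
#' unnormalized weight `1/p` when `x == prev`, `1` when `x` is adjacent to
#' `prev`, and `1/q` otherwise, then weights are normalized to probabilities.
#'
#' @param graph a [term_graph()]
#' @param prev,curr the previous and current node; `{prev, curr}` must be an
#'   edge of `graph`
#' @param p,q walk bias parameters (see [walk_params()])
#' @return named numeric vector of probabilities over the neighbors of `curr`,
#'   summing to 1
#' @export
#' @examples
#' g <- term_graph(rbind(c("t", "v"), c("v", "x1"), c("v", "x2"), c("t", "x1")))
#' transition_distribution(g, "t", "v", p = 0.25, q = 4)
transition_distribution <- function(graph, prev, curr, p = 0.25, q = 4) {
  stopifnot(p > 0, q > 0)
  it <- match(prev, graph$nodes)
  iv <- match(curr, graph$nodes)
  if (is.na(it) || is.na(iv)) stop("prev/curr not in graph")
  nbv <- graph$adj[[iv]]
  if (!(it %in% nbv)) stop("prev is not adjacent to curr")
  w <- transition_weights(graph$adj, it, iv, p, q)
  pr <- w / sum(w)
  names(pr) <- graph$nodes[nbv]
  pr
}

# unnormalized second-order weights over adj[[iv]] given predecessor it
transition_weights <- function(adj, it, iv, p, q) {
  nbv <- adj[[iv]]
  w <- rep(1 / q, length(nbv))
  w[match(adj[[it]], nbv, nomatch = 0L)] <- 1
  w[nbv == it] <- 1 / p
  w
}

#' Generate one biased random walk
#'
#' Walks `params$l` nodes starting from `start`. The first step (which has no
#' predecessor) is uniform over the neighbors of `start`; subsequent steps
#' follow [transition_distribution()]. An isolated start node yields the
#' length-1 sequence `[start]`. Draws come from R's RNG; seed the session (or
#' use [graph_seq_gen()], which seeds internally) for reproducibility.
#'
#' @inheritParams transition_distribution
#' @param start the start node
#' @param params a [walk_params()]
#' @return character vector of visited nodes
#' @export
node2vec_walk <- function(graph, start, params = walk_params()) {
  s <- match(start, graph$nodes)
  if (is.na(s)) stop(sprintf("start node '%s' not in graph", start))
  graph$nodes[walk_ids(graph$adj, s, params$l, params$p, params$q)]
}

walk_ids <- function(adj, start, l, p, q) {
  path <- integer(l)
  path[1L] <- start
  if (l == 1L) return(path)
  nb <- adj[[start]]
  if (length(nb) == 0L) return(path[1L])
  path[2L] <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
  if (l >= 3L) {
    for (i in 3:l) {
      it <- path[i - 2L]
      iv <- path[i - 1L]
      nbv <- adj[[iv]]
      if (length(nbv) == 1L) {
        path[i] <- nbv
      } else {
        w <- transition_weights(adj, it, iv, p, q)
        path[i] <- nbv[sample.int(length(nbv), 1L, prob = w)]
      }
    }
  }
  path
}

#' Generate a sequence set from a graph by repeated biased walks
#'
#' Starts `params$r` walks of length `params$l` from every node of the graph
#' (isolated nodes contribute length-1 sequences so that every vocabulary
#' term still appears in training). Fully reproducible given `params$seed`.
#'
#' @inheritParams transition_distribution
#' @param params a [walk_params()]
#' @param source source tag for the resulting [sequence_set()]
#' @return a [sequence_set()] with `r * n_nodes(graph)` sequences
#' @export
graph_seq_gen <- function(graph, params = walk_params(), source = "predications") {
  if (n_nodes(graph) == 0L) stop("graph is empty")
  adj <- graph$adj
  n <- n_nodes(graph)
  with_rng_seed(params$seed, {
    seqs <- vector("list", params$r * n)
    k <- 0L
    for (rep in seq_len(params$r)) {
      for (v in seq_len(n)) {
        k <- k + 1L
        seqs[[k]] <- graph$nodes[walk_ids(adj, v, params$l, params$p, params$q)]
      }
    }
    sequence_set(seqs, source = source)
  })
}

#' Convert a corpus to sequences by uniform permutation sampling
#'
#' Each document (a term set) becomes one sequence: a uniformly random
#' permutation of its full term set.
#'
#' @param corpus a [term_corpus()]
#' @param seed integer seed
#' @return a [sequence_set()] with one sequence per document, tagged `"corpus"`
#' @export
corpus_to_sequences <- function(corpus, seed = 1L) {
  stopifnot(inherits(corpus, "term_corpus"))
  with_rng_seed(seed, {
    sequence_set(lapply(corpus$documents, function(d) d[sample.int(length(d))]),
                 source = "corpus")
  })
}
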