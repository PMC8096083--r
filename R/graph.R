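#' Term graphs
#'
#' A `term_graph` is a simple undirected graph over a controlled vocabulary of
#' term tokens: no self-loops, no duplicate edges, and every edge has unit
#' weight. Ontology and predication inputs arrive directed (child -> parent,
#' subject -> object) but are stored and walked undirected; the original
#' orientation, when known, is retained for export only.
#'
#' @param edges character matrix with two columns (endpoints of each edge) or
#'   a two-element character vector for a single edge. Self-loops and
#'   duplicate edges (in either orientation) are dropped and counted.
#' @param nodes optional character vector of node tokens; defaults to all edge
#'   endpoints. Must cover every endpoint. Extra tokens become isolated nodes.
#' @param directed_edges optional character matrix preserving the input
#'   orientation (used by [write_edge_list()] when `directed = TRUE`).
#' @param blocks optional named integer vector of diagnostic block labels
#'   (names are node tokens), as produced by [make_planted_graph()].
#'
#' @return an object of class `term_graph` with elements `nodes` (character),
#'   `edges` (2-column character matrix, canonical order), and attributes
#'   `dropped` (count of discarded input edges) and `blocks`.
#' @export
#' @examples
#' g <- term_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
#' n_nodes(g)
#' n_edges(g)
term_graph <- function(edges, nodes = NULL, directed_edges = NULL,
                       blocks = NULL) {
  if (is.vector(edges) && !is.list(edges)) {
    edges <- matrix(edges, ncol = 2L)
  }
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  stopifnot(is.matrix(edges), ncol(edges) == 2L)
  edges <- matrix(as.character(edges), ncol = 2L)
  if (any(!nzchar(edges)) || any(grepl("[[:space:]]", edges))) {
    stop("term tokens must be non-empty and contain no whitespace")
  }
  nodes <- unique(c(nodes, as.vector(t(edges))))
  if (any(!nzchar(nodes)) || any(grepl("[[:space:]]", nodes))) {
    stop("term tokens must be non-empty and contain no whitespace")
  }

  n_in <- nrow(edges)
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  # canonical unordered form, dedup across both orientations
  swap <- edges[, 1L] > edges[, 2L]
  tmp <- edges[swap, 1L]
  edges[swap, 1L] <- edges[swap, 2L]
  edges[swap, 2L] <- tmp
  dup <- duplicated(paste(edges[, 1L], edges[, 2L], sep = "\t"))
  edges <- edges[!dup, , drop = FALSE]
  dropped <- n_in - nrow(edges)

  ids <- seq_along(nodes)
  names(ids) <- nodes
  eu <- ids[edges[, 1L]]
  ev <- ids[edges[, 2L]]
  adj <- vector("list", length(nodes))
  for (i in ids) adj[[i]] <- integer()
  if (length(eu)) {
    adj_from <- split(c(ev, eu), c(eu, ev))
    for (k in names(adj_from)) {
      adj[[as.integer(k)]] <- sort(unique(adj_from[[k]]))
    }
  }

  structure(
    list(nodes = nodes,
         edges = edges,
         edge_ids = cbind(u = unname(eu), v = unname(ev)),
         adj = adj,
         directed_edges = directed_edges,
         blocks = blocks,
         dropped = dropped),
    class = "term_graph"
  )
}

#' @rdname term_graph
#' @param g a `term_graph`
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname term_graph
#' @export
n_edges <- function(g) nrow(g$edges)

#' @export
print.term_graph <- function(x, ...) {
  cat(sprintf("term_graph: %d nodes, %d edges", n_nodes(x), n_edges(x)))
  if (!is.null(x$blocks)) cat(sprintf(", %d blocks", length(unique(x$blocks))))
  if (x$dropped > 0) cat(sprintf(" (%d input edges dropped)", x$dropped))
  cat("\n")
  invisible(x)
}

#' Neighbors of a node
#'
#' @param g a [term_graph()]
#' @param node a term token
#' @return character vector of neighboring tokens (possibly empty)
#' @export
neighbors_of <- function(g, node) {
  id <- match(node, g$nodes)
  if (is.na(id)) stop(sprintf("node '%s' not in graph", node))
  g$nodes[g$adj[[id]]]
}

#' Test whether an unordered pair is an edge
#'
#' @inheritParams neighbors_of
#' @param u,v term tokens
#' @export
has_edge <- function(g, u, v) {
  iu <- match(u, g$nodes)
  iv <- match(v, g$nodes)
  if (is.na(iu) || is.na(iv)) return(FALSE)
  iv %in% g$adj[[iu]]
}

#' Convert to an igraph object
#'
#' Undirected view used for bridge finding and connectivity checks.
#'
#' @inheritParams neighbors_of
#' @return an [igraph::graph] object with vertex names
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_nodes(g), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
  if (n_edges(g) > 0) {
    ig <- igraph::add_edges(ig, t(g$edge_ids))
  }
  ig
}

#' Read a term graph from an edge list file
#'
#' Each non-comment line holds at least two whitespace-separated tokens; the
#' first two are the edge endpoints (ontology files are child -> parent,
#' predication files subject -> object). Lines starting with `#` are ignored.
#' The graph is stored undirected and simple: self-loops and duplicate edges
#' are dropped, and the number of dropped input edges is reported via a
#' message and kept in the `dropped` element of the result.
#'
#' @param path path to the edge-list file
#' @param directed_input whether to retain the input orientation for later
#'   directed export (the walk view is always undirected)
#' @return a [term_graph()]
#' @export
read_edge_list <- function(path, directed_input = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no edges in '", path, "'")
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge at line %d of '%s': need >= 2 tokens",
                 line_no[bad[1L]], path))
  }
  em <- cbind(vapply(toks, `[[`, "", 1L), vapply(toks, `[[`, "", 2L))
  g <- term_graph(em, directed_edges = if (directed_input) em else NULL)
  if (g$dropped > 0) {
    message(sprintf("read_edge_list: dropped %d self-loop/duplicate edges",
                    g$dropped))
  }
  g
}

#' Write a term graph as an edge list
#'
#' @param g a [term_graph()]
#' @param path output file path
#' @param directed if `TRUE` and the graph retained its input orientation,
#'   write that orientation; otherwise write the canonical undirected form.
#' @export
write_edge_list <- function(g, path, directed = FALSE) {
  em <- if (directed && !is.null(g$directed_edges)) g$directed_edges else g$edges
  writeLines(paste(em[, 1L], em[, 2L], sep = "\t"), path)
  invisible(path)
}
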