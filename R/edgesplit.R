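#' Bridge edges of a graph
#'
#' Bridges are the edges whose removal increases the number of connected
#' components. They must all be kept in the training split so that the
#' training graph preserves the connectivity of the source graph.
#'
#' @param graph a [term_graph()]
#' @return two-column character matrix of bridge edges (canonical order)
#' @export
find_bridges <- function(graph) {
  if (n_nodes(graph) == 0L) stop("graph is empty")
  if (n_edges(graph) == 0L) return(graph$edges)
  ig <- as_igraph(graph)
  b <- igraph::bridges(ig)
  if (length(b) == 0L) return(graph$edges[0L, , drop = FALSE])
  em <- igraph::ends(ig, b)
  swap <- em[, 1L] > em[, 2L]
  tmp <- em[swap, 1L]; em[swap, 1L] <- em[swap, 2L]; em[swap, 2L] <- tmp
  em
}

#' Split positive edges 50/25/25 with bridge preservation
#'
#' Partitions the edge set into train/validation/test positives such that the
#' train graph has exactly the same connected components as the source graph.
#' The training split starts from a random spanning forest of the graph —
#' which necessarily contains every bridge edge, so all bridges end up in
#' train — and is filled to its quota (`ceiling(ratios[1] * |E|)`) with the
#' remaining edges shuffled under `seed`; validation takes the next
#' `ceiling(ratios[2] * |E|)` and test the remainder. (Keeping the bridges
#' alone would not suffice: removing two edges of one cycle can disconnect a
#' graph even though neither is a bridge.) If the forest alone exceeds the
#' train quota, train keeps the whole forest and the remaining edges are
#' split equally between validation and test (with a warning if either ends
#' up empty). The connectivity invariant is asserted internally after the
#' split.
#'
#' @param graph a [term_graph()] with at least 4 edges
#' @param ratios train/validation/test fractions, summing to 1
#' @param seed integer seed for the shuffle
#' @return list with two-column character matrices `train`, `valid`, `test`,
#'   plus `bridges` and the `seed`
#' @export
split_edges <- function(graph, ratios = c(0.5, 0.25, 0.25), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-8)
  m <- n_edges(graph)
  if (m < 4L) stop("graph too small to split (need >= 4 edges)")
  bridges <- find_bridges(graph)
  key <- paste(graph$edges[, 1L], graph$edges[, 2L], sep = "\t")

  n_tr <- min(m, ceiling(ratios[1L] * m))
  with_rng_seed(seed, {
    # random spanning forest: run a forest-growing pass over shuffled edges
    ord <- sample.int(m)
    comp <- seq_len(n_nodes(graph))  # union-find over node ids
    find_root <- function(i) {
      while (comp[i] != i) {
        comp[i] <<- comp[comp[i]]
        i <- comp[i]
      }
      i
    }
    in_forest <- logical(m)
    for (e in ord) {
      ru <- find_root(graph$edge_ids[e, 1L])
      rv <- find_root(graph$edge_ids[e, 2L])
      if (ru != rv) {
        comp[ru] <- rv
        in_forest[e] <- TRUE
      }
    }
    rest <- which(!in_forest)[sample.int(sum(!in_forest))]
    if (sum(in_forest) > n_tr) {
      train_idx <- which(in_forest)
      n_va <- floor(length(rest) / 2)
      valid_idx <- rest[seq_len(n_va)]
      test_idx <- setdiff(rest, valid_idx)
    } else {
      fill <- rest[seq_len(n_tr - sum(in_forest))]
      train_idx <- c(which(in_forest), fill)
      rest2 <- setdiff(rest, fill)
      n_va <- min(length(rest2), ceiling(ratios[2L] * m))
      valid_idx <- rest2[seq_len(n_va)]
      test_idx <- setdiff(rest2, valid_idx)
    }
  })
  if (length(valid_idx) == 0L || length(test_idx) == 0L) {
    warning("bridge-dominated graph: empty validation and/or test split")
  }

  train <- graph$edges[train_idx, , drop = FALSE]
  # connectivity invariant: train subgraph has the same components
  tg <- term_graph(train, nodes = graph$nodes)
  n_comp_src <- igraph::count_components(as_igraph(graph))
  n_comp_tr <- igraph::count_components(as_igraph(tg))
  stopifnot(n_comp_tr == n_comp_src)

  list(train = train,
       valid = graph$edges[valid_idx, , drop = FALSE],
       test = graph$edges[test_idx, , drop = FALSE],
       bridges = bridges,
       seed = as.integer(seed))
}

#' Sample negative (absent) edges
#'
#' Draws unordered pairs of distinct nodes of `graph` that are not edges,
#' uniformly without replacement, and deals them into three pairwise-disjoint
#' sets matching the requested counts — the balanced negatives for the
#' train/validation/test splits.
#'
#' @param graph a [term_graph()]
#' @param counts integer vector `(n_train, n_valid, n_test)`
#' @param seed integer seed
#' @return list of two-column character matrices `train`, `valid`, `test`
#' @export
sample_negative_edges <- function(graph, counts, seed = 1L) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  counts <- as.integer(counts)
  total <- sum(counts)
  n <- n_nodes(graph)
  n_pairs <- n * (n - 1) / 2
  n_non <- n_pairs - n_edges(graph)
  if (n_non < total) {
    stop(sprintf("need %d non-edges but the graph has only %.0f", total, n_non))
  }
  edge_key <- pair_keys(graph$edge_ids[, 1L], graph$edge_ids[, 2L])

  with_rng_seed(seed, {
    if (n_pairs <= 5e5) {
      cmb <- utils::combn(n, 2L)
      keys <- pair_keys(cmb[1L, ], cmb[2L, ])
      non <- which(!(keys %in% edge_key))
      pick <- non[sample.int(length(non), total)]
      um <- cmb[1L, pick]
      vm <- cmb[2L, pick]
    } else {
      seen <- character(0)
      um <- integer(0); vm <- integer(0)
      while (length(um) < total) {
        a <- sample.int(n, 2L * (total - length(um)) + 16L, replace = TRUE)
        b <- sample.int(n, length(a), replace = TRUE)
        ok <- a != b
        a <- a[ok]; b <- b[ok]
        k <- pair_keys(a, b)
        keep <- !(k %in% edge_key) & !(k %in% seen) & !duplicated(k)
        um <- c(um, a[keep]); vm <- c(vm, b[keep])
        seen <- c(seen, k[keep])
        if (length(um) > total) {
          um <- um[seq_len(total)]; vm <- vm[seq_len(total)]
        }
      }
    }
  })

  canon <- cbind(graph$nodes[pmin(um, vm)], graph$nodes[pmax(um, vm)])
  idx <- c(0L, cumsum(counts))
  out <- lapply(1:3, function(i) {
    canon[seq(idx[i] + 1L, length.out = counts[i]), , drop = FALSE]
  })
  names(out) <- c("train", "valid", "test")
  out
}

#' Build a full labeled edge split
#'
#' Convenience wrapper combining [split_edges()] and
#' [sample_negative_edges()] into one `edge_split` object with balanced
#' positives and negatives per split.
#'
#' @param graph a [term_graph()] (the predication graph)
#' @param ratios train/validation/test fractions
#' @param seed integer seed (positives shuffle and negative draws)
#' @return an `edge_split`: lists `pos` and `neg`, each with `train`/`valid`/
#'   `test` two-column matrices, plus `seed`
#' @export
make_edge_split <- function(graph, ratios = c(0.5, 0.25, 0.25), seed = 1L) {
  pos <- split_edges(graph, ratios, seed = derive_seed(seed, 11L))
  neg <- sample_negative_edges(
    graph,
    counts = c(nrow(pos$train), nrow(pos$valid), nrow(pos$test)),
    seed = derive_seed(seed, 12L)
  )
  structure(list(pos = pos[c("train", "valid", "test")], neg = neg,
                 bridges = pos$bridges, seed = as.integer(seed)),
            class = "edge_split")
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf(
    "edge_split: train %d+/%d-, valid %d+/%d-, test %d+/%d- (%d bridges)\n",
    nrow(x$pos$train), nrow(x$neg$train), nrow(x$pos$valid), nrow(x$neg$valid),
    nrow(x$pos$test), nrow(x$neg$test), nrow(x$bridges)))
  invisible(x)
}

#' Write an edge split as labeled TSV files
#'
#' Writes `train.tsv`, `valid.tsv`, `test.tsv` with columns `u`, `v`,
#' `label` (1 = positive, 0 = negative).
#'
#' @param split an [make_edge_split()] result
#' @param dir output directory (created if missing)
#' @export
write_edge_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("train", "valid", "test")) {
    p <- split$pos[[part]]; n <- split$neg[[part]]
    df <- data.frame(u = c(p[, 1L], n[, 1L]), v = c(p[, 2L], n[, 2L]),
                     label = c(rep(1L, nrow(p)), rep(0L, nrow(n))))
    utils::write.table(df, file.path(dir, paste0(part, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a labeled edge TSV written by [write_edge_split()]
#'
#' @param path path to a `u v label` TSV
#' @return data.frame with character `u`, `v` and integer `label`
#' @export
read_labeled_edges <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer"))
  stopifnot(all(c("u", "v", "label") %in% names(df)))
  df
}
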