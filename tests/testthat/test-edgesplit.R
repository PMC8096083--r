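test_that("bridge finding matches tree/cycle closed forms and a removal oracle", {
  # every edge of a tree is a bridge
  tree <- term_graph(rbind(c("a", "b"), c("b", "c"), c("b", "d"), c("d", "e")))
  expect_equal(nrow(find_bridges(tree)), 4)
  # a cycle has none
  cyc <- term_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  expect_equal(nrow(find_bridges(cyc)), 0)

  for (seed in 1:50) {
    g <- rand_graph(12, 0.2, seed = seed)
    got <- find_bridges(g)
    want <- bf_bridges(g)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
})

test_that("edge split hits the 50/25/25 sizes with all bridges in train", {
  # 24 nodes, 100 edges, 10 of them bridges: K14 minus one edge + pendant path
  core <- sprintf("c%02d", 1:14)
  cmb <- utils::combn(14, 2)
  dense <- cbind(core[cmb[1, ]], core[cmb[2, ]])[-1, ]  # 90 edges
  path <- cbind(c(core[1], sprintf("p%02d", 1:9)), sprintf("p%02d", 1:10))
  g <- term_graph(rbind(dense, path))
  expect_equal(n_edges(g), 100)
  expect_equal(nrow(find_bridges(g)), 10)

  sp <- split_edges(g, seed = 7)
  expect_equal(nrow(sp$train), 50)
  expect_equal(nrow(sp$valid), 25)
  expect_equal(nrow(sp$test), 25)
  train_keys <- paste(sp$train[, 1], sp$train[, 2])
  expect_true(all(paste(sp$bridges[, 1], sp$bridges[, 2]) %in% train_keys))

  expect_error(split_edges(term_graph(rbind(c("a", "b"), c("b", "c"))), seed = 1),
               "too small")
})

test_that("bridge-dominated graphs keep connectivity and warn on empty splits", {
  path <- term_graph(cbind(sprintf("v%03d", 1:99), sprintf("v%03d", 2:100)))
  expect_warning(sp <- split_edges(path, seed = 3), "empty")
  expect_equal(nrow(sp$train), 99)
  expect_equal(nrow(sp$valid) + nrow(sp$test), 0)
})

test_that("splits partition the edges and preserve connectivity", {
  for (seed in 1:30) {
    set.seed(seed)
    g <- rand_graph(sample(10:20, 1), runif(1, 0.2, 0.6), seed = seed * 31)
    if (n_edges(g) < 4) next
    # sparse draws can be bridge-dominated; that warning is asserted above
    sp <- suppressWarnings(split_edges(g, seed = seed))
    keys <- sort(c(paste(sp$train[, 1], sp$train[, 2]),
                   paste(sp$valid[, 1], sp$valid[, 2]),
                   paste(sp$test[, 1], sp$test[, 2])))
    expect_equal(keys, sort(paste(g$edges[, 1], g$edges[, 2])))
    # oracle: component labels of every node pair agree
    tg <- term_graph(sp$train, nodes = g$nodes)
    mem_src <- igraph::components(as_igraph(g))$membership
    mem_tr <- igraph::components(as_igraph(tg))$membership
    expect_true(all(outer(mem_src, mem_src, "==") ==
                    outer(mem_tr[names(mem_src)], mem_tr[names(mem_src)], "==")))
  }
})

test_that("negative sampling avoids edges and returns disjoint balanced sets", {
  # complete graph: no non-edges at all
  k4 <- term_graph(t(utils::combn(c("a", "b", "c", "d"), 2)))
  expect_error(sample_negative_edges(k4, c(1, 1, 1)), "non-edges")

  g <- term_graph(rbind(c("A", "B")), nodes = c("A", "B", "C", "D"))
  neg <- sample_negative_edges(g, c(1, 1, 1), seed = 5)
  pairs <- rbind(neg$train, neg$valid, neg$test)
  keys <- paste(pairs[, 1], pairs[, 2])
  expect_equal(length(unique(keys)), 3)
  expect_false(any(keys %in% c("A B", "B A")))
  all_non <- c("A C", "A D", "B C", "B D", "C D")
  expect_true(all(keys %in% all_non))

  for (seed in 1:10) {
    g2 <- rand_graph(15, 0.3, seed = seed)
    sp <- make_edge_split(g2, seed = seed)
    for (part in c("train", "valid", "test")) {
      expect_equal(nrow(sp$neg[[part]]), nrow(sp$pos[[part]]))
      nk <- paste(sp$neg[[part]][, 1], sp$neg[[part]][, 2])
      ek <- c(paste(g2$edges[, 1], g2$edges[, 2]),
              paste(g2$edges[, 2], g2$edges[, 1]))
      expect_false(any(nk %in% ek))
    }
    nks <- lapply(sp$neg, function(m) paste(m[, 1], m[, 2]))
    expect_equal(length(unique(unlist(nks))), length(unlist(nks)))
  }
})

test_that("labeled edge splits round trip through TSV", {
  g <- rand_graph(12, 0.4, seed = 2)
  sp <- make_edge_split(g, seed = 2)
  dir <- withr::local_tempdir()
  write_edge_split(sp, dir)
  tr <- read_labeled_edges(file.path(dir, "train.tsv"))
  expect_equal(sum(tr$label == 1), nrow(sp$pos$train))
  expect_equal(sum(tr$label == 0), nrow(sp$neg$train))
  expect_setequal(paste(tr$u[tr$label == 1], tr$v[tr$label == 1]),
                  paste(sp$pos$train[, 1], sp$pos$train[, 2]))
})
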