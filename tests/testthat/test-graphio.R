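test_that("edge-list reading parses, simplifies and counts drops", {
  f <- withr::local_tempfile(lines = c("# comment", "A B", "B C"))
  g <- read_edge_list(f)
  expect_equal(n_nodes(g), 3)
  expect_equal(n_edges(g), 2)
  expect_equal(g$dropped, 0)

  f2 <- withr::local_tempfile(lines = c("A B", "B A", "A A"))
  expect_message(g2 <- read_edge_list(f2), "dropped 2")
  expect_equal(n_nodes(g2), 2)
  expect_equal(n_edges(g2), 1)
  expect_equal(g2$dropped, 2)

  expect_error(read_edge_list(withr::local_tempfile(lines = "# only comments")),
               "no edges")
  expect_error(read_edge_list(withr::local_tempfile(lines = c("A B", "C"))),
               "line 2")
})

test_that("large random edge file matches a naive set-based re-parse", {
  set.seed(42)
  toks <- sprintf("v%02d", 1:40)
  lines <- replicate(1000, paste(sample(toks, 2), collapse = "\t"))
  f <- withr::local_tempfile(lines = lines)
  g <- suppressMessages(read_edge_list(f))
  # oracle: line-by-line canonical-pair set
  pairs <- unique(vapply(strsplit(lines, "\t"), function(x) {
    paste(sort(x), collapse = "|")
  }, ""))
  pairs <- pairs[!grepl("^(.+)\\|\\1$", pairs)]
  expect_equal(n_edges(g), length(pairs))
  expect_equal(sort(g$nodes), sort(unique(unlist(strsplit(lines, "\t")))))
})

test_that("parsed graphs are always simple", {
  for (seed in 1:10) {
    set.seed(seed)
    lines <- replicate(200, paste(sample(sprintf("x%d", 1:12), 2,
                                         replace = TRUE), collapse = " "))
    f <- withr::local_tempfile(lines = lines)
    g <- suppressMessages(read_edge_list(f))
    expect_false(any(g$edges[, 1] == g$edges[, 2]))
    expect_false(any(duplicated(paste(g$edges[, 1], g$edges[, 2]))))
    # canonical order means no reversed duplicates either
    expect_true(all(g$edges[, 1] < g$edges[, 2]))
  }
})

test_that("corpus reading collapses duplicates and drops singletons", {
  f <- withr::local_tempfile(lines = c("A B C", "A A B", "A"))
  expect_message(co <- read_corpus(f), "dropped 1")
  expect_equal(length(co$documents), 2)
  expect_setequal(co$documents[[1]], c("A", "B", "C"))
  expect_setequal(co$documents[[2]], c("A", "B"))
  expect_error(read_corpus(withr::local_tempfile(lines = character())),
               "no documents")
  expect_error(term_corpus(list(c("A", "B"), "C")), ">= 2 distinct")
})

test_that("embedding word2vec round trip is lossless within tolerance", {
  set.seed(7)
  tab <- embedding_table(matrix(rnorm(6), 2, 3,
                                dimnames = list(c("alpha", "beta"), NULL)))
  f <- withr::local_tempfile()
  write_embeddings(tab, f)
  lines <- readLines(f)
  expect_length(lines, 3)
  expect_equal(lines[1], "2 3")
  back <- read_embeddings(f)
  expect_equal(unclass(back)[rownames(tab), ], unclass(tab)[, ],
               tolerance = 1e-6, ignore_attr = TRUE)

  f1 <- withr::local_tempfile(lines = c("1 2", "A 0.5 -0.5"))
  one <- read_embeddings(f1)
  expect_equal(unname(one["A", ]), c(0.5, -0.5))

  fbad <- withr::local_tempfile(lines = c("2 3", "A 1 2 3", "B 1 2"))
  expect_error(read_embeddings(fbad), "expected 3")
  fbad2 <- withr::local_tempfile(lines = c("3 2", "A 1 2", "B 1 2"))
  expect_error(read_embeddings(fbad2), "declares 3")
})

test_that("corpus and sequence files round trip", {
  co <- term_corpus(list(c("A", "B", "C"), c("D", "E")))
  f <- withr::local_tempfile()
  write_corpus(co, f)
  expect_equal(read_corpus(f)$documents, co$documents)

  s <- sequence_set(list(c("A", "B"), c("C", "A", "B")),
                    source = c("corpus", "ontology"))
  f2 <- withr::local_tempfile()
  write_sequences(s, f2)
  expect_equal(read_sequences(f2)$sequences, s$sequences)
})
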