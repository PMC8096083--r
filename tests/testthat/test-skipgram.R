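test_that("context pairs follow the span-k window convention", {
  p <- context_pairs(c("a", "b", "c"), k = 5)
  expect_equal(nrow(p), 6)
  expect_setequal(paste(p[, 1], p[, 2]),
                  c("a b", "a c", "b a", "b c", "c a", "c b"))

  expect_equal(nrow(context_pairs("a", k = 5)), 0)

  # k = 3 means one context term per side
  p3 <- context_pairs(letters[1:6], k = 3)
  expect_equal(nrow(p3), 10)
  counts <- table(p3[, 1])
  expect_equal(unname(counts[c("a", "f")]), c(1L, 1L), ignore_attr = TRUE)
  expect_true(all(counts[c("b", "c", "d", "e")] == 2))

  expect_error(context_pairs(letters[1:3], k = 4))
})

test_that("full-softmax likelihood matches closed form and a brute-force loop", {
  terms <- letters[1:4]
  zero <- embedding_table(matrix(0, 4, 3, dimnames = list(terms, NULL)))
  s <- sequence_set(list(c("a", "b", "c")))
  expect_equal(full_softmax_log_likelihood(zero, s, k = 5), 6 * log(1 / 4))

  # independent double loop over pairs and vocabulary
  tab <- random_embedding(letters[1:5], d = 4, seed = 3, sd = 0.7)
  set.seed(8)
  sqs <- replicate(3, sample(letters[1:5], sample(2:5, 1)), simplify = FALSE)
  ss <- sequence_set(sqs)
  want <- 0
  for (sq in sqs) {
    n <- length(sq)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || abs(i - j) > 2) next
        num <- sum(tab[sq[j], ] * tab[sq[i], ])
        den <- 0
        for (u in letters[1:5]) den <- den + exp(sum(tab[u, ] * tab[sq[i], ]))
        want <- want + num - log(den)
      }
    }
  }
  expect_equal(full_softmax_log_likelihood(tab, ss, k = 5), want,
               tolerance = 1e-10)
})

test_that("analytic negative-sampling gradient matches central differences", {
  terms <- letters[1:6]
  tab <- random_embedding(terms, d = 5, seed = 11, sd = 0.5)
  # duplicate negative and a self-negative exercise accumulation paths
  cases <- list(c("a", "b", "c", "d"), c("a", "b", "b", "e"),
                c("c", "d", "c", "c"), c("e", "f", "a", "a"))
  for (cs in cases) {
    center <- cs[1]; context <- cs[2]; negs <- cs[-(1:2)]
    grad <- sgns_pair_grad(tab, center, context, negs)
    eps <- 1e-5
    for (t0 in unique(cs)) {
      for (k in seq_len(ncol(tab))) {
        up <- tab; up[t0, k] <- up[t0, k] + eps
        dn <- tab; dn[t0, k] <- dn[t0, k] - eps
        num <- (sgns_pair_objective(up, center, context, negs) -
                sgns_pair_objective(dn, center, context, negs)) / (2 * eps)
        denom <- max(abs(num), abs(grad[t0, k]), 1e-8)
        expect_lt(abs(num - grad[t0, k]) / denom, 1e-5)
      }
    }
  }
})

test_that("negative draws are uniform over the vocabulary", {
  draws <- meshwalk:::sgns_draw_negatives_cpp(100000L, 20L, 7L)
  freq <- table(factor(draws, levels = 1:20)) / 100000
  expect_lt(max(abs(freq - 1 / 20)), 0.01)
})

test_that("training improves the exact objective and is deterministic", {
  s <- two_cluster_sequences(n_docs = 60, seed = 5)
  cfg <- skipgram_config(dim = 16, epochs = 3, seed = 21)
  emb <- train_skipgram(s, cfg)
  expect_equal(dim(emb), c(10, 16))
  expect_setequal(rownames(emb), c(paste0("a", 1:5), paste0("b", 1:5)))

  init <- random_embedding(rownames(emb), d = 16, seed = 1)
  expect_gt(full_softmax_log_likelihood(emb, s),
            full_softmax_log_likelihood(init, s))

  emb2 <- train_skipgram(s, cfg)
  expect_identical(unclass(emb), unclass(emb2))
  emb3 <- train_skipgram(s, skipgram_config(dim = 16, epochs = 3, seed = 22))
  expect_false(identical(unclass(emb), unclass(emb3)))

  expect_error(train_skipgram(sequence_set(list("a", "b")), cfg),
               "nothing to train on")
})

test_that("co-occurrence clusters separate in embedding space", {
  wins <- 0
  for (run in 1:100) {
    s <- two_cluster_sequences(n_docs = 30, seed = run)
    emb <- train_skipgram(s, skipgram_config(dim = 8, epochs = 2,
                                             seed = 1000 + run))
    E <- emb / sqrt(rowSums(emb^2))
    S <- E %*% t(E)
    grp <- substr(rownames(emb), 1, 1)
    same <- outer(grp, grp, "==") & upper.tri(S)
    diff <- (!outer(grp, grp, "==")) & upper.tri(S)
    if (mean(S[same]) > mean(S[diff])) wins <- wins + 1
  }
  expect_gte(wins, 95)
})
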