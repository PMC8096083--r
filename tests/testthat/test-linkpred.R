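test_that("edge embedding is the symmetric component-wise mean", {
  tab <- embedding_table(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE,
                                dimnames = list(c("u", "v"), NULL)))
  expect_equal(unname(edge_embedding(tab, "u", "v")[1, ]), c(2, 3))
  expect_equal(unname(edge_embedding(tab, "u", "u")[1, ]), c(1, 2))
  expect_error(edge_embedding(tab, "u", "w"), "w")

  big <- random_embedding(sprintf("t%02d", 1:20), d = 6, seed = 3, sd = 1)
  set.seed(4)
  for (i in 1:50) {
    uv <- sample(rownames(big), 2)
    expect_equal(edge_embedding(big, uv[1], uv[2]),
                 edge_embedding(big, uv[2], uv[1]), ignore_attr = TRUE)
  }
})

test_that("classifier separates linear blobs and stops early on noise", {
  set.seed(10)
  n <- 200
  x <- rbind(matrix(rnorm(n, mean = 2), n / 2, 2),
             matrix(rnorm(n, mean = -2), n / 2, 2))
  y <- rep(c(1L, 0L), each = n / 2)
  idx <- sample(n)
  tr <- idx[1:150]; va <- idx[151:200]
  cfg <- classifier_config(hidden = 32, max_epochs = 200, seed = 6)
  m <- train_edge_classifier(x[tr, ], y[tr], x[va, ], y[va], cfg)
  acc <- mean(predict(m, x[tr, ], type = "class") == y[tr])
  expect_gte(acc, 0.99)

  # shuffled labels: validation loss cannot keep improving, patience fires
  set.seed(11)
  ysh <- sample(y)
  m2 <- train_edge_classifier(x[tr, ], ysh[tr], x[va, ], ysh[va],
                              classifier_config(hidden = 32, seed = 6))
  expect_lt(m2$epochs_run, 2000)
  expect_equal(m2$epochs_run, m2$best_epoch + m2$config$patience)

  # same seed, same trajectory
  m3 <- train_edge_classifier(x[tr, ], y[tr], x[va, ], y[va], cfg)
  expect_identical(m$val_losses, m3$val_losses)

  expect_error(train_edge_classifier(x[tr, ], rep(1L, 150), x[va, ], y[va], cfg),
               "both classes")
})

test_that("ranking metrics match hand-worked examples", {
  # perfect ordering
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # step-interpolated AP on a mixed ranking
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6)
  # reversal identity
  set.seed(1)
  sc <- runif(40); lb <- rep(c(0, 1), 20)
  expect_equal(auroc(sc, lb), 1 - auroc(-sc, lb))
  # null distribution
  set.seed(2)
  expect_lt(abs(auroc(runif(10000), rep(c(0, 1), 5000)) - 0.5), 0.02)
})

test_that("all six metrics agree with brute-force sweeps on small sets", {
  set.seed(33)
  for (i in 1:150) {
    n <- sample(4:12, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    thr <- runif(1)
    rep <- metrics_report(scores, labels, threshold = thr)
    expect_equal(unname(rep["auroc"]), bf_auroc(scores, labels))
    expect_equal(unname(rep["map"]), bf_average_precision(scores, labels))
    expect_equal(unname(rep["auprc"]), bf_auprc(scores, labels))
    expect_equal(unname(rep[c("precision", "recall", "f1")]),
                 bf_macro_prf(scores, labels, thr))
    expect_true(all(rep >= 0 & rep <= 1))
  }
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- rnorm(200); lb <- rbinom(200, 1, plogis(sc))
  if (length(unique(lb)) == 2) {
    expect_equal(auroc(sc, lb),
                 as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))))
  }
})

test_that("repeated-run t-test behaves at the boundaries and calibrates", {
  expect_equal(repeated_runs_ttest(1:5, 1:5), 1)
  expect_lt(repeated_runs_ttest(c(0, 0, 0, 0.01), c(10, 10, 10, 10.01)), 0.001)
  expect_error(repeated_runs_ttest(rep(1, 3), rep(2, 4)), "zero variance")

  set.seed(12)
  rej <- mean(replicate(1000, {
    repeated_runs_ttest(rnorm(6), rnorm(6)) < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.025)
})
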