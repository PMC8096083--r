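#' Run the full multi-source embedding and edge-prediction pipeline
#'
#' Executes the complete protocol on one predication graph:
#' \enumerate{
#'   \item split the predication edges 50/25/25 with bridge preservation and
#'     sample balanced negatives ([make_edge_split()]);
#'   \item generate term sequences from each requested source — biased random
#'     walks on the ontology and on the graph of \emph{training} positives
#'     only (so embedding learning never sees validation/test edges; this is
#'     asserted), and uniform permutations of the corpus documents;
#'   \item equalize and merge the per-source sequence sets
#'     ([merge_sources()]);
#'   \item train skip-gram embeddings on the merged set ([train_skipgram()]);
#'   \item represent each candidate edge by the average of its endpoint
#'     vectors, train the early-stopped classifier on the train split, and
#'     report the six metrics on the test split.
#' }
#' One master seed drives every stage through fixed offsets
#' ([derive_seed()]), so two runs with the same inputs and seed are
#' identical.
#'
#' @param predications [term_graph()] of the target predication edges
#' @param ontology optional ontology [term_graph()]
#' @param corpus optional [term_corpus()]
#' @param sources character subset of
#'   `c("corpus", "ontology", "predications")` to learn embeddings from
#'   (source-ablation runs pass a subset); each requested source must be
#'   supplied
#' @param strategy merge strategy, see [merge_sources()]
#' @param walk a [walk_params()] (its `seed` is overridden per stage)
#' @param sg a [skipgram_config()] (its `seed` is overridden)
#' @param clf a [classifier_config()] (its `seed` is overridden)
#' @param average P/R/F1 averaging convention
#' @param seed master seed
#' @param out_dir optional directory; when given, all intermediates (splits,
#'   sequence files, merged sequences, embeddings, report and manifest JSON)
#'   are written there
#' @return a `pipeline_result` list: `metrics` ([metrics_report()]),
#'   `embeddings`, `split`, `classifier`, `sources`, `strategy`, `seed`
#' @export
run_pipeline <- function(predications, ontology = NULL, corpus = NULL,
                         sources = c("corpus", "ontology", "predications"),
                         strategy = c("up", "up_down", "none"),
                         walk = walk_params(), sg = skipgram_config(),
                         clf = classifier_config(),
                         average = c("macro", "micro"),
                         seed = 1L, out_dir = NULL) {
  strategy <- match.arg(strategy)
  average <- match.arg(average)
  sources <- match.arg(sources, several.ok = TRUE)
  stopifnot(inherits(predications, "term_graph"))
  if ("ontology" %in% sources && is.null(ontology)) {
    stop("source 'ontology' requested but no ontology given")
  }
  if ("corpus" %in% sources && is.null(corpus)) {
    stop("source 'corpus' requested but no corpus given")
  }

  split <- make_edge_split(predications, seed = derive_seed(seed, 1L))

  # walk graph: training positives only, over the full predication node set
  train_graph <- term_graph(split$pos$train, nodes = predications$nodes)
  held_out <- rbind(split$pos$valid, split$pos$test)
  leaked <- mapply(has_edge, u = held_out[, 1L], v = held_out[, 2L],
                   MoreArgs = list(g = train_graph))
  if (any(leaked)) stop("leakage guard: held-out edge present in walk graph")

  sets <- list()
  if ("corpus" %in% sources) {
    sets$corpus <- corpus_to_sequences(corpus, seed = derive_seed(seed, 2L))
  }
  if ("ontology" %in% sources) {
    wo <- walk; wo$seed <- derive_seed(seed, 3L)
    sets$ontology <- graph_seq_gen(ontology, wo, source = "ontology")
  }
  if ("predications" %in% sources) {
    ws <- walk; ws$seed <- derive_seed(seed, 4L)
    sets$predications <- graph_seq_gen(train_graph, ws, source = "predications")
  }

  merged <- merge_sources(sets, strategy = strategy,
                          seed = derive_seed(seed, 5L))

  sg$seed <- derive_seed(seed, 6L)
  emb <- train_skipgram(merged, sg)

  feats <- function(part) {
    pairs <- rbind(split$pos[[part]], split$neg[[part]])
    list(x = edge_embedding(emb, pairs[, 1L], pairs[, 2L]),
         y = c(rep(1L, nrow(split$pos[[part]])),
               rep(0L, nrow(split$neg[[part]]))))
  }
  all_terms <- unique(as.vector(rbind(
    split$pos$train, split$pos$valid, split$pos$test,
    split$neg$train, split$neg$valid, split$neg$test)))
  missing <- setdiff(all_terms, rownames(emb))
  if (length(missing)) {
    stop(sprintf("%d split endpoints have no embedding (e.g. %s); include a source that covers the vocabulary",
                 length(missing), missing[1L]))
  }

  tr <- feats("train"); va <- feats("valid"); te <- feats("test")
  clf$seed <- derive_seed(seed, 7L)
  model <- train_edge_classifier(tr$x, tr$y, va$x, va$y, clf)
  metrics <- evaluate_classifier(model, te$x, te$y, average = average)

  result <- structure(
    list(metrics = metrics, embeddings = emb, split = split,
         classifier = model, sources = sources, strategy = strategy,
         seed = as.integer(seed)),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_edge_split(split, file.path(out_dir, "splits"))
    for (nm in names(sets)) {
      write_sequences(sets[[nm]], file.path(out_dir, paste0("seqs_", nm, ".txt")))
    }
    write_sequences(merged, file.path(out_dir, "seqs_merged.txt"))
    write_embeddings(emb, file.path(out_dir, "embeddings.w2v"))
    jsonlite::write_json(as.list(unclass(metrics)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package = "meshwalk",
      version = as.character(utils::packageVersion("meshwalk")),
      seed = seed, sources = sources, strategy = strategy,
      walk = unclass(walk)[c("p", "q", "r", "l")],
      skipgram = unclass(sg)[c("dim", "window", "negative", "epochs",
                               "alpha", "alpha_min")],
      classifier = unclass(clf)[c("hidden", "max_epochs", "patience",
                                  "batch_size", "lr")],
      sizes = list(nodes = n_nodes(predications),
                   edges = n_edges(predications),
                   sequences = n_sequences(merged)),
      stage_seeds = list(split = derive_seed(seed, 1L),
                         corpus = derive_seed(seed, 2L),
                         ontology_walks = derive_seed(seed, 3L),
                         predication_walks = derive_seed(seed, 4L),
                         merge = derive_seed(seed, 5L),
                         skipgram = derive_seed(seed, 6L),
                         classifier = derive_seed(seed, 7L)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (sources: %s; strategy: %s; seed %d)\n",
              paste(x$sources, collapse = "+"), x$strategy, x$seed))
  print(x$metrics)
  invisible(x)
}

#' Repeat the pipeline over several seeds
#'
#' Runs [run_pipeline()] with master seeds `seed, seed + 1, ...` and collects
#' the per-run test metrics, mirroring the repeated-runs protocol used to
#' average out initialization noise before significance testing.
#'
#' @inheritParams run_pipeline
#' @param runs number of repetitions
#' @param ... passed on to [run_pipeline()]
#' @return data.frame with one row per run (columns: seed + the six metrics)
#' @export
run_repeated <- function(predications, ontology = NULL, corpus = NULL,
                         runs = 10L, seed = 1L, ...) {
  rows <- lapply(seq_len(runs) - 1L, function(i) {
    res <- run_pipeline(predications, ontology = ontology, corpus = corpus,
                        seed = seed + i, ...)
    c(seed = seed + i, unclass(res$metrics))
  })
  as.data.frame(do.call(rbind, rows))
}
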