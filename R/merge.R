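#' Sample a sequence set with replacement
#'
#' @param s a [sequence_set()]
#' @param size number of sequences to draw (>= 1)
#' @return a [sequence_set()] of exactly `size` sequences drawn with
#'   replacement from `s`, source tags preserved. Uses the current RNG state;
#'   callers that need reproducibility seed first (as [merge_sources()] does).
#' @export
sample_with_replacement <- function(s, size) {
  stopifnot(inherits(s, "sequence_set"))
  if (n_sequences(s) == 0L) stop("cannot sample from an empty sequence set")
  if (!is.numeric(size) || length(size) != 1L || size < 1L) {
    stop("size must be a positive integer")
  }
  idx <- sample.int(n_sequences(s), as.integer(size), replace = TRUE)
  sequence_set(s$sequences[idx], source = s$source[idx])
}

#' Equalize and merge sequence sets from several data sources
#'
#' Implements the sampling-and-merging step of the embedding framework and
#' its ablation variants:
#' \describe{
#'   \item{`"up"`}{each source smaller than the largest is up-sampled with
#'     replacement to `N = max(sizes)`; the largest source passes through
#'     unchanged. Afterwards every source contributes exactly `N` sequences.}
#'   \item{`"up_down"`}{the up-sampled pool is re-sampled with replacement
#'     down to the original total `sum(sizes)`, so source balance is kept in
#'     expectation but the corpus volume is not inflated.}
#'   \item{`"none"`}{plain concatenation of the sources.}
#' }
#' The result is a multiset: duplicates created by up-sampling are kept, and
#' the merged order is shuffled under `seed`.
#'
#' @param sets named list of [sequence_set()] objects (>= 1, all non-empty);
#'   passing fewer than three sources supports source-ablation runs
#' @param strategy one of `"up"`, `"up_down"`, `"none"`
#' @param seed integer seed for the resampling and the final shuffle
#' @return a [sequence_set()]; each sequence keeps its originating source tag
#' @export
merge_sources <- function(sets, strategy = c("up", "up_down", "none"),
                          seed = 1L) {
  strategy <- match.arg(strategy)
  if (inherits(sets, "sequence_set")) sets <- list(sets)
  stopifnot(is.list(sets), length(sets) >= 1L)
  for (s in sets) {
    if (!inherits(s, "sequence_set")) stop("all sources must be sequence_set objects")
    if (n_sequences(s) == 0L) stop("all sources must be non-empty")
  }
  sizes <- vapply(sets, n_sequences, 0L)
  total <- sum(sizes)

  with_rng_seed(seed, {
    pooled <- switch(
      strategy,
      none = sets,
      up = {
        n_max <- max(sizes)
        lapply(sets, function(s) {
          if (n_sequences(s) == n_max) s else sample_with_replacement(s, n_max)
        })
      },
      up_down = {
        n_max <- max(sizes)
        up <- lapply(sets, function(s) {
          if (n_sequences(s) == n_max) s else sample_with_replacement(s, n_max)
        })
        pool <- concat_sets(up)
        list(sample_with_replacement(pool, total))
      }
    )
    merged <- concat_sets(pooled)
    ord <- sample.int(n_sequences(merged))
    sequence_set(merged$sequences[ord], source = merged$source[ord])
  })
}

concat_sets <- function(sets) {
  sequence_set(unname(do.call(c, lapply(sets, `[[`, "sequences"))),
               source = unname(do.call(c, lapply(sets, `[[`, "source"))))
}
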