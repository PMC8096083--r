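#' Skip-gram training configuration
#'
#' The window parameter `k` is the total span of the context window centered
#' on a term, so `k = 5` means up to `(k - 1) / 2 = 2` context terms on each
#' side (this differs from the word2vec convention where `window = 5` means 5
#' per side). Negative samples are drawn from a uniform distribution over the
#' vocabulary, not the 3/4-power unigram distribution. Dimension 128 and
#' window 5 are the fixed settings of the original study; negatives = 5,
#' epochs = 5 and the 0.025 -> 1e-4 linear learning-rate decay are standard
#' skip-gram defaults.
#'
#' @param dim embedding dimension d (>= 1)
#' @param window window span k (odd, >= 3)
#' @param negative negative samples per positive pair (>= 1)
#' @param epochs passes over the sequence set (>= 1)
#' @param alpha initial learning rate
#' @param alpha_min floor of the linearly decayed learning rate
#' @param seed integer seed (initialization + negative draws)
#' @return a `skipgram_config` list
#' @export
skipgram_config <- function(dim = 128L, window = 5L, negative = 5L,
                            epochs = 5L, alpha = 0.025, alpha_min = 1e-4,
                            seed = 1L) {
  stopifnot(dim >= 1, window >= 3, window %% 2 == 1, negative >= 1,
            epochs >= 1, alpha > 0, alpha_min > 0)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 negative = as.integer(negative), epochs = as.integer(epochs),
                 alpha = alpha, alpha_min = alpha_min, seed = as.integer(seed)),
            class = "skipgram_config")
}

#' Enumerate (center, context) pairs of a sequence
#'
#' For every position, emits a pair with each of the up to `(k - 1) / 2`
#' terms on either side (the center itself excluded), truncated at the
#' sequence boundaries.
#'
#' @param s character vector (a term sequence)
#' @param k window span (odd, >= 3)
#' @return two-column character matrix with columns `center`, `context`
#' @export
#' @examples
#' context_pairs(c("a", "b", "c"), k = 5)
context_pairs <- function(s, k = 5L) {
  stopifnot(k >= 3, k %% 2 == 1)
  n <- length(s)
  half <- (k - 1L) %/% 2L
  if (n < 2L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("center", "context"))))
  }
  centers <- integer(); contexts <- integer()
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    j <- j[j != i]
    centers <- c(centers, rep(i, length(j)))
    contexts <- c(contexts, j)
  }
  matrix(c(s[centers], s[contexts]), ncol = 2L,
         dimnames = list(NULL, c("center", "context")))
}

#' Exact full-softmax skip-gram log-likelihood
#'
#' The exact objective that negative sampling approximates: the sum over all
#' (center, context) pairs of `log softmax(f(context)' f(center))` where the
#' softmax normalizes over the whole vocabulary (the rows of `table`). Only
#' practical for small vocabularies; used as the oracle that training must
#' improve.
#'
#' @param table an [embedding_table()] covering every term in `s`
#' @param s a [sequence_set()]
#' @param k window span (odd, >= 3)
#' @return a scalar log-likelihood (0 when there are no context pairs)
#' @export
full_softmax_log_likelihood <- function(table, s, k = 5L) {
  stopifnot(inherits(s, "sequence_set"))
  ll <- 0
  for (sq in s$sequences) {
    pairs <- context_pairs(sq, k)
    if (nrow(pairs) == 0L) next
    ic <- match(pairs[, 1L], rownames(table))
    io <- match(pairs[, 2L], rownames(table))
    if (anyNA(ic) || anyNA(io)) stop("sequence term missing from embedding table")
    scores <- table %*% t(table[ic, , drop = FALSE])  # |V| x n_pairs
    dots <- scores[cbind(io, seq_along(io))]
    mx <- apply(scores, 2L, max)
    lse <- mx + log(colSums(exp(sweep(scores, 2L, mx))))
    ll <- ll + sum(dots - lse)
  }
  ll
}

#' Negative-sampling objective and gradient for one training event
#'
#' The per-pair surrogate that the trainer ascends:
#' `log sigmoid(f(w)' f(c)) + sum_u log sigmoid(-f(w)' f(u))` for center `w`,
#' context `c`, and negative terms `u`, with a single shared vector table.
#' `sgns_pair_grad()` returns the analytic gradient with respect to every row
#' of the table (rows not involved get zero; repeated negatives accumulate).
#' Exposed mainly so the gradient can be verified against finite differences.
#'
#' @param table an [embedding_table()]
#' @param center,context term tokens
#' @param negatives character vector of negative-sample tokens
#' @return `sgns_pair_objective()`: a scalar; `sgns_pair_grad()`: a matrix of
#'   the same shape as `table`
#' @export
sgns_pair_objective <- function(table, center, context, negatives) {
  w <- embedding_vectors(table, center)[1L, ]
  cv <- embedding_vectors(table, context)[1L, ]
  uu <- embedding_vectors(table, negatives)
  log_sigmoid(sum(w * cv)) + sum(log_sigmoid(-drop(uu %*% w)))
}

#' @rdname sgns_pair_objective
#' @export
sgns_pair_grad <- function(table, center, context, negatives) {
  grad <- matrix(0, nrow(table), ncol(table), dimnames = dimnames(table))
  iw <- match(center, rownames(table))
  ic <- match(context, rownames(table))
  iu <- match(negatives, rownames(table))
  if (anyNA(c(iw, ic, iu))) stop("term missing from embedding table")
  w <- table[iw, ]
  cv <- table[ic, ]
  g <- 1 - sigmoid(sum(w * cv))
  grad[iw, ] <- grad[iw, ] + g * cv
  grad[ic, ] <- grad[ic, ] + g * w
  for (i in iu) {
    gu <- -sigmoid(sum(w * table[i, ]))
    grad[iw, ] <- grad[iw, ] + gu * table[i, ]
    grad[i, ] <- grad[i, ] + gu * w
  }
  grad
}

sigmoid <- function(x) 1 / (1 + exp(-x))

log_sigmoid <- function(x) ifelse(x > -30, -log1p(exp(-x)), x)

#' Train skip-gram embeddings with uniform negative sampling
#'
#' Learns one shared d-dimensional vector per term occurring in `s` by
#' stochastic gradient ascent on the negative-sampling surrogate of the
#' skip-gram likelihood. Deterministic given `cfg$seed` (single-threaded).
#'
#' @param s a [sequence_set()] yielding at least one context pair
#' @param cfg a [skipgram_config()]
#' @return an [embedding_table()] covering every term in `s`
#' @export
train_skipgram <- function(s, cfg = skipgram_config()) {
  stopifnot(inherits(s, "sequence_set"), inherits(cfg, "skipgram_config"))
  vocab <- sort(unique(unlist(s$sequences, use.names = FALSE)))
  iseqs <- lapply(s$sequences, function(x) match(x, vocab))
  half <- (cfg$window - 1L) %/% 2L
  mat <- sgns_train_cpp(iseqs, length(vocab), cfg$dim, half, cfg$negative,
                        cfg$epochs, cfg$alpha, cfg$alpha_min, cfg$seed)
  rownames(mat) <- vocab
  embedding_table(mat)
}
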