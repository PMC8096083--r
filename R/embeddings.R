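#' Embedding tables
#'
#' An embedding table maps each term to a d-dimensional real vector. It is
#' represented as a numeric matrix with one row per term; row names are the
#' term tokens.
#'
#' @param mat numeric matrix with unique, non-empty row names
#' @return the validated matrix with class `embedding_table`
#' @export
embedding_table <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat), nrow(mat) > 0L, ncol(mat) > 0L)
  rn <- rownames(mat)
  if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn))) {
    stop("embedding table needs unique non-empty row names")
  }
  class(mat) <- c("embedding_table", class(mat))
  mat
}

#' @rdname embedding_table
#' @param table an `embedding_table`
#' @export
embedding_dim <- function(table) ncol(table)

#' Look up term vectors
#'
#' @param table an [embedding_table()]
#' @param terms character vector of term tokens
#' @return matrix of vectors, one row per requested term
#' @export
embedding_vectors <- function(table, terms) {
  idx <- match(terms, rownames(table))
  if (anyNA(idx)) {
    stop("terms missing from embedding table: ",
         paste(utils::head(terms[is.na(idx)], 5L), collapse = ", "))
  }
  table[idx, , drop = FALSE]
}

#' Write embeddings in word2vec text format
#'
#' Header line `"<N> <d>"`, then one line per term:
#' `"<token> v1 v2 ... vd"`. Round-tripping reproduces every component to
#' within 1e-6.
#'
#' @param table an [embedding_table()]
#' @param path output path
#' @export
write_embeddings <- function(table, path) {
  stopifnot(nrow(table) > 0L)
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(rownames(table)[i],
          paste(sprintf("%.10g", table[i, ]), collapse = " "))
  }, "")
  writeLines(c(sprintf("%d %d", nrow(table), ncol(table)), rows), path)
  invisible(path)
}

#' Read embeddings in word2vec text format
#'
#' @param path path to a word2vec text file
#' @return an [embedding_table()]
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("embedding file '", path, "' too short")
  hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  if (length(hdr) != 2L) stop("bad header in '", path, "'")
  n <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop(sprintf("header declares %d rows but file has %d", n, length(body)))
  }
  toks <- strsplit(trimws(body), "[[:space:]]+")
  if (any(lengths(toks) != d + 1L)) {
    bad <- which(lengths(toks) != d + 1L)[1L]
    stop(sprintf("row %d has %d values, expected %d", bad,
                 lengths(toks)[bad] - 1L, d))
  }
  terms <- vapply(toks, `[[`, "", 1L)
  mat <- matrix(as.numeric(unlist(lapply(toks, `[`, -1L), use.names = FALSE)),
                nrow = n, ncol = d, byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric vector component in '", path, "'")
  rownames(mat) <- terms
  embedding_table(mat)
}
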