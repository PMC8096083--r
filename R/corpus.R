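#' Term-set corpora and term sequences
#'
#' A `term_corpus` is a list of documents, each a set (no duplicates) of at
#' least two term tokens — the "document as indexing-term set" view of a
#' bibliographic corpus. A `sequence_set` is a multiset of term sequences
#' tagged by the data source that produced them; duplicates are permitted
#' because up-sampling deliberately creates them.
#'
#' @param documents list of character vectors; duplicates within a document
#'   are collapsed, and every document must retain >= 2 distinct terms
#' @return a `term_corpus`
#' @export
term_corpus <- function(documents) {
  stopifnot(is.list(documents), length(documents) > 0L)
  documents <- lapply(documents, function(d) unique(as.character(d)))
  if (any(lengths(documents) < 2L)) {
    stop("every document needs >= 2 distinct terms")
  }
  structure(list(documents = documents), class = "term_corpus")
}

#' @export
print.term_corpus <- function(x, ...) {
  cat(sprintf("term_corpus: %d documents, %d distinct terms\n",
              length(x$documents), length(unique(unlist(x$documents)))))
  invisible(x)
}

#' Read a corpus file
#'
#' One document per line, whitespace-separated term tokens. Duplicate tokens
#' within a line are collapsed; lines with fewer than two distinct tokens are
#' dropped and counted (reported via message and the `dropped` attribute).
#'
#' @param path path to the corpus file
#' @return a [term_corpus()]
#' @export
read_corpus <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no documents in '", path, "'")
  docs <- lapply(strsplit(lines, "[[:space:]]+"), unique)
  keep <- lengths(docs) >= 2L
  dropped <- sum(!keep)
  docs <- docs[keep]
  if (length(docs) == 0L) stop("no documents with >= 2 distinct terms in '", path, "'")
  if (dropped > 0) {
    message(sprintf("read_corpus: dropped %d documents with < 2 distinct terms",
                    dropped))
  }
  out <- term_corpus(docs)
  attr(out, "dropped") <- dropped
  out
}

#' Write a corpus file
#'
#' @param corpus a [term_corpus()]
#' @param path output path
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus$documents, paste, "", collapse = " "), path)
  invisible(path)
}

#' Sequence sets
#'
#' @param sequences list of character vectors (term sequences, length >= 1)
#' @param source a source tag per sequence, one of `"corpus"`, `"ontology"`,
#'   `"predications"`, `"merged"`; recycled if length 1
#' @return a `sequence_set`
#' @export
sequence_set <- function(sequences, source = "merged") {
  stopifnot(is.list(sequences))
  if (any(lengths(sequences) < 1L)) stop("sequences must have length >= 1")
  sequences <- lapply(sequences, as.character)
  if (length(source) == 1L) source <- rep(source, length(sequences))
  stopifnot(length(source) == length(sequences))
  structure(list(sequences = sequences, source = source),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  tab <- table(x$source)
  cat(sprintf("sequence_set: %d sequences (%s)\n", length(x$sequences),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @rdname sequence_set
#' @param s a `sequence_set`
#' @export
n_sequences <- function(s) length(s$sequences)

#' Read / write sequence files
#'
#' One sequence per line, space-separated tokens.
#'
#' @param path file path
#' @param source tag attached to every read sequence
#' @return [read_sequences()] returns a [sequence_set()]
#' @export
read_sequences <- function(path, source = "merged") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no sequences in '", path, "'")
  sequence_set(strsplit(lines, "[[:space:]]+"), source = source)
}

#' @rdname read_sequences
#' @param s a [sequence_set()]
#' @export
write_sequences <- function(s, path) {
  writeLines(vapply(s$sequences, paste, "", collapse = " "), path)
  invisible(path)
}
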