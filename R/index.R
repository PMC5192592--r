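#' Build the semantic index over a corpus
#'
#' Constructs everything both relatedness measures need: body-field statistics
#' and the sparse body weight matrix `B` (documents by body terms, retrieval
#' weights, one column per term acting as a posting list sorted by document),
#' precomputed document norms, and the title matrix `C` (title terms by
#' documents, binary-tf idf weights). All construction is deterministic given
#' the corpus, the stopword list and `min_df`, so rebuilding on identical
#' input yields an identical index.
#'
#' @param corpus Corpus tibble (`doc_id`, `title`, `body`).
#' @param stopwords Stopword list.
#' @param min_df Document-frequency floor for title terms (default 3).
#' @return A `semantic_index` object.
#' @export
#' @examples
#' corpus <- generate_corpus(synthetic_config(n_topics = 2, docs_per_topic = 5))
#' idx <- build_semantic_index(corpus)
#' idx
build_semantic_index <- function(corpus, stopwords = default_stopwords(),
                                 min_df = 3L) {
  corpus <- validate_corpus(corpus)
  if (nrow(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  body_stats <- build_field_statistics(corpus, "body", min_df = 1L,
                                       stopwords = stopwords)
  title_stats <- build_field_statistics(corpus, "title", min_df = min_df,
                                        stopwords = stopwords)
  n <- nrow(corpus)

  # body matrix: docs x terms, Lucene-style weights
  body_toks <- tokenize(corpus$body, stopwords)
  vocab <- names(body_stats$df)
  tf_tabs <- lapply(body_toks, function(tk) table(tk))
  ii <- rep.int(seq_len(n), vapply(tf_tabs, length, integer(1)))
  terms <- unlist(lapply(tf_tabs, names), use.names = FALSE)
  tfs <- as.numeric(unlist(tf_tabs, use.names = FALSE))
  if (length(terms) > 0L) {
    jj <- match(terms, vocab)
    dfj <- as.numeric(body_stats$df[jj])
    lens <- as.numeric(body_stats$doc_length[ii])
    w <- sqrt(tfs) * (1 + log(n / (dfj + 1)))^2 / sqrt(lens)
    B <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, length(vocab)),
                              dimnames = list(corpus$doc_id, vocab))
  } else {
    B <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, length(vocab)),
                              dimnames = list(corpus$doc_id, vocab))
  }
  doc_norms <- sqrt(Matrix::rowSums(B^2))

  C <- build_title_matrix(corpus, title_stats)

  structure(
    list(
      corpus = corpus,
      stopwords = stopwords,
      min_df = as.integer(min_df),
      body_stats = body_stats,
      title_stats = title_stats,
      B = B,
      doc_norms = doc_norms,
      C = C
    ),
    class = "semantic_index"
  )
}

#' @export
print.semantic_index <- function(x, ...) {
  cat("<semantic_index>\n")
  cat("  documents:        ", nrow(x$corpus), "\n", sep = "")
  cat("  body vocabulary:  ", length(x$body_stats$df), " terms\n", sep = "")
  cat("  title vocabulary: ", length(x$title_stats$df),
      " terms (min_df=", x$min_df, ")\n", sep = "")
  cat("  title-space dim / corpus size: ",
      signif(length(x$title_stats$df) / nrow(x$corpus), 3), "\n", sep = "")
  invisible(x)
}

#' Persist a semantic index to a directory
#'
#' Plain-text layout: a JSON metadata file, the stopword list, per-field
#' statistics as TSV sidecars, and the two sparse matrices in MatrixMarket
#' format with their dimension names alongside, so an index reloads without
#' re-scanning the corpus.
#'
#' @param index A `semantic_index`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_semantic_index()]
#' @export
write_semantic_index <- function(index, dir) {
  stopifnot(inherits(index, "semantic_index"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  jsonlite::write_json(
    list(format_version = 1L, n_docs = nrow(index$corpus),
         min_df = index$min_df),
    p("meta.json"), auto_unbox = TRUE
  )
  writeLines(index$stopwords, p("stopwords.txt"), useBytes = TRUE)
  readr::write_tsv(tibble::tibble(term = names(index$body_stats$df),
                                  df = as.integer(index$body_stats$df)),
                   p("body_df.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(term = names(index$title_stats$df),
                                  df = as.integer(index$title_stats$df)),
                   p("title_df.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(doc_id = names(index$body_stats$doc_length),
                                  length = as.integer(index$body_stats$doc_length)),
                   p("doc_length.tsv"), progress = FALSE)
  Matrix::writeMM(index$B, p("body_matrix.mtx"))
  Matrix::writeMM(index$C, p("title_matrix.mtx"))
  write_corpus(index$corpus, p("corpus.jsonl"), "jsonl")
  invisible(dir)
}

#' Load a semantic index written by [write_semantic_index()]
#'
#' Reconstructs the index from the persisted statistics and matrices; the
#' corpus text is loaded for reference but not re-scanned.
#'
#' @param dir Index directory.
#' @return A `semantic_index`.
#' @export
read_semantic_index <- function(dir) {
  p <- function(...) file.path(dir, ...)
  if (!file.exists(p("meta.json"))) {
    stop("not a semantic index directory (no meta.json): ", dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(p("meta.json"))
  corpus <- read_corpus(p("corpus.jsonl"), "jsonl")
  stopwords <- readLines(p("stopwords.txt"), encoding = "UTF-8", warn = FALSE)
  body_df <- readr::read_tsv(p("body_df.tsv"), col_types = "ci", progress = FALSE)
  title_df <- readr::read_tsv(p("title_df.tsv"), col_types = "ci", progress = FALSE)
  doc_len <- readr::read_tsv(p("doc_length.tsv"), col_types = "ci", progress = FALSE)
  n <- as.integer(meta$n_docs)
  if (n != nrow(corpus)) {
    stop("index directory is inconsistent: meta.json n_docs disagrees with ",
         "the stored corpus", call. = FALSE)
  }
  body_stats <- structure(list(
    field = "body", N = n,
    df = stats::setNames(body_df$df, body_df$term),
    doc_length = stats::setNames(doc_len$length, doc_len$doc_id),
    min_df = 1L, stopwords = stopwords
  ), class = "field_stats")
  title_stats <- structure(list(
    field = "title", N = n,
    df = stats::setNames(title_df$df, title_df$term),
    doc_length = NULL, min_df = as.integer(meta$min_df), stopwords = stopwords
  ), class = "field_stats")
  B <- methods::as(Matrix::readMM(p("body_matrix.mtx")), "CsparseMatrix")
  dimnames(B) <- list(doc_len$doc_id, body_df$term)
  C <- methods::as(Matrix::readMM(p("title_matrix.mtx")), "CsparseMatrix")
  dimnames(C) <- list(title_df$term, doc_len$doc_id)
  structure(
    list(corpus = corpus, stopwords = stopwords,
         min_df = as.integer(meta$min_df),
         body_stats = body_stats, title_stats = title_stats,
         B = B, doc_norms = sqrt(Matrix::rowSums(B^2)), C = C),
    class = "semantic_index"
  )
}
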