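#' Title matrix C
#'
#' The sparse title-term by document matrix whose column `i` is the binary-tf
#' idf vector of document `i`'s title: `C[j, i] = idf(term_j)` when term `j`
#' occurs in title `i` (however many times), zero otherwise. Terms removed by
#' the `min_df` floor contribute no rows. Rows are sorted by term, columns
#' follow corpus order, so rebuilding is deterministic.
#'
#' @param corpus Corpus tibble.
#' @param title_stats Title `field_stats` built with the `min_df` floor.
#' @param top_idf_cap Optional per-title cap: keep at most this many
#'   highest-idf terms per title (ties broken by term string). Default
#'   `Inf` — the `min_df` floor already keeps titles short.
#' @return A sparse `dgCMatrix` (title terms x documents).
#' @export
build_title_matrix <- function(corpus, title_stats, top_idf_cap = Inf) {
  stopifnot(inherits(title_stats, "field_stats"), title_stats$field == "title")
  corpus <- validate_corpus(corpus)
  vocab <- names(title_stats$df)
  idf_w <- log(title_stats$N / as.numeric(title_stats$df))
  toks <- lapply(tokenize(corpus$title, title_stats$stopwords), unique)
  toks <- lapply(toks, function(tk) sort(tk[tk %in% vocab]))
  if (is.finite(top_idf_cap)) {
    toks <- lapply(toks, function(tk) {
      if (length(tk) <= top_idf_cap) return(tk)
      o <- order(-idf_w[match(tk, vocab)], tk)
      sort(tk[o[seq_len(top_idf_cap)]])
    })
  }
  jj <- rep.int(seq_len(nrow(corpus)), lengths(toks))
  ii <- match(unlist(toks, use.names = FALSE), vocab)
  x <- idf_w[ii]
  keep <- which(x > 0)
  Matrix::sparseMatrix(
    i = ii[keep], j = jj[keep], x = x[keep],
    dims = c(length(vocab), nrow(corpus)),
    dimnames = list(vocab, corpus$doc_id)
  )
}

#' tESA vector of a doc vector
#'
#' Transforms a (truncated) doc vector into title space: the weight of title
#' term `j` is the sum over doc-vector entries `i` of `weight_i * C[j, i]` —
#' a sparse matrix-vector product with the title matrix. Terms with zero sum
#' are absent. The accumulation order is fixed by the matrix layout, so the
#' result is reproducible bit-for-bit on one platform.
#'
#' @param index A `semantic_index`.
#' @param dv Doc vector tibble (`doc_id`, `weight`), usually from
#'   [doc_vector()].
#' @return Tibble with columns `term`, `weight`, sorted by term; zero rows
#'   for an empty doc vector.
#' @export
tesa_vector <- function(index, dv) {
  stopifnot(inherits(index, "semantic_index"))
  stopifnot(is.data.frame(dv), all(c("doc_id", "weight") %in% names(dv)))
  if (nrow(dv) == 0L) {
    return(tibble::tibble(term = character(0), weight = numeric(0)))
  }
  j <- match(dv$doc_id, colnames(index$C))
  if (anyNA(j)) {
    stop("doc vector references unknown doc_id: ",
         paste(utils::head(dv$doc_id[is.na(j)], 3), collapse = ", "),
         call. = FALSE)
  }
  o <- order(j)  # fixed ascending-document accumulation order
  w <- as.numeric(index$C[, j[o], drop = FALSE] %*% dv$weight[o])
  keep <- which(w > 0)
  tibble::tibble(term = rownames(index$C)[keep], weight = w[keep])
}

#' Semantic representation of a free text under either measure
#'
#' Convenience wrapper producing the final representation vector used for
#' relatedness: the truncated doc vector for ESA, or its title-space
#' transform for tESA.
#'
#' @param index A `semantic_index`.
#' @param text Raw input text.
#' @param method `"tesa"` or `"esa"`.
#' @param M Doc-vector truncation bound (default 10000).
#' @param top Keep only the `top` heaviest entries of the result for display
#'   (default all).
#' @return Tibble with the key column (`term` for tESA, `doc_id` for ESA)
#'   and `weight`, sorted by decreasing weight.
#' @export
semantic_vector <- function(index, text, method = c("tesa", "esa"),
                            M = 10000L, top = Inf) {
  method <- match.arg(method)
  dv <- doc_vector(index, text, M = M)
  out <- if (method == "esa") dv else tesa_vector(index, dv)
  key <- names(out)[1]
  o <- order(-out$weight, out[[key]])
  out <- out[o, , drop = FALSE]
  if (is.finite(top)) out <- utils::head(out, top)
  tibble::as_tibble(out)
}
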