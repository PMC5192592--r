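#' Doc vector of a free-text input
#'
#' The ESA representation: one entry per corpus document, equal to the cosine
#' between the body-space tf-idf vector of the input and the body tf-idf
#' vector of that document, keeping only the `M` largest weights. Documents
#' with zero score are absent. Entries are returned sorted by decreasing
#' weight, ties broken by ascending `doc_id`, which makes truncation
#' deterministic across platforms.
#'
#' @param index A `semantic_index`.
#' @param query Raw input text, or a pre-tokenized character vector with
#'   `tokenized = TRUE`.
#' @param M Truncation bound on the number of retained entries
#'   (default 10000).
#' @param tokenized Set `TRUE` when `query` is already tokenized.
#' @return Tibble with columns `doc_id`, `weight`; zero rows when no input
#'   token is covered by the body vocabulary.
#' @export
doc_vector <- function(index, query, M = 10000L, tokenized = FALSE) {
  stopifnot(inherits(index, "semantic_index"))
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("M must be a positive integer", call. = FALSE)
  q <- query_vector(query, index$body_stats, tokenized = tokenized)
  empty <- tibble::tibble(doc_id = character(0), weight = numeric(0))
  if (nrow(q) == 0L) return(empty)
  j <- match(q$term, colnames(index$B))
  num <- as.numeric(index$B[, j, drop = FALSE] %*% q$weight)
  qn <- sqrt(sum(q$weight^2))
  keep <- which(num > 0 & index$doc_norms > 0)
  if (length(keep) == 0L) return(empty)
  dv <- tibble::tibble(
    doc_id = rownames(index$B)[keep],
    weight = num[keep] / (index$doc_norms[keep] * qn)
  )
  truncate_doc_vector(dv, M)
}

#' Truncate a doc vector to its M heaviest entries
#'
#' Keeps the `M` largest weights; ties at the boundary are resolved by
#' ascending `doc_id` so the result is deterministic. With `M` at or above
#' the entry count this is the identity (modulo the canonical ordering).
#'
#' @param dv Doc vector tibble (`doc_id`, `weight`).
#' @param M Positive integer bound.
#' @return Doc vector tibble with at most `M` rows, sorted by decreasing
#'   weight then ascending `doc_id`.
#' @export
truncate_doc_vector <- function(dv, M) {
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("M must be a positive integer", call. = FALSE)
  stopifnot(is.data.frame(dv), all(c("doc_id", "weight") %in% names(dv)))
  o <- order(-dv$weight, dv$doc_id)
  dv <- dv[o, , drop = FALSE]
  tibble::as_tibble(utils::head(dv, M))
}
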