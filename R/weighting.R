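#' Per-field corpus statistics
#'
#' Scans one field (title or body) of every document and records the corpus
#' size `N`, the per-term document frequency `df` (number of distinct
#' documents whose field contains the term), and — for the body field — the
#' token count of each document, which feeds length normalization. Title
#' statistics apply the `min_df` floor; body statistics are unfiltered.
#'
#' @param corpus Corpus tibble (`doc_id`, `title`, `body`).
#' @param field `"body"` or `"title"`.
#' @param min_df Document-frequency floor, applied to the title field only
#'   (default 3 for titles, 1 for bodies).
#' @param stopwords Stopword list used during tokenization.
#' @return A `field_stats` object: list with `field`, `N`, `df` (named
#'   integer vector, terms sorted), `doc_length` (body only), `min_df`, and
#'   the `stopwords` used, so downstream vectorizers tokenize consistently.
#' @export
build_field_statistics <- function(corpus, field = c("body", "title"),
                                   min_df = NULL,
                                   stopwords = default_stopwords()) {
  field <- match.arg(field)
  corpus <- validate_corpus(corpus)
  if (nrow(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  if (is.null(min_df)) min_df <- if (field == "title") 3L else 1L
  min_df <- as.integer(min_df)
  if (is.na(min_df) || min_df < 1L) stop("min_df must be >= 1", call. = FALSE)

  toks <- tokenize(corpus[[field]], stopwords)
  per_doc <- lapply(toks, unique)
  all_terms <- unlist(per_doc, use.names = FALSE)
  if (length(all_terms) > 0L) {
    tab <- table(all_terms)
    df <- stats::setNames(as.integer(tab), names(tab))
    df <- df[order(names(df))]
  } else {
    df <- stats::setNames(integer(0), character(0))
  }
  if (field == "title") df <- df[df >= min_df]

  out <- list(
    field = field,
    N = nrow(corpus),
    df = df,
    doc_length = if (field == "body") {
      stats::setNames(lengths(toks), corpus$doc_id)
    } else NULL,
    min_df = if (field == "title") min_df else 1L,
    stopwords = stopwords
  )
  class(out) <- "field_stats"
  out
}

#' @export
print.field_stats <- function(x, ...) {
  cat("<field_stats> field=", x$field, "  N=", x$N,
      "  vocabulary=", length(x$df), " terms", sep = "")
  if (x$field == "title") cat("  (min_df=", x$min_df, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Inverse document frequency
#'
#' `idf(t) = log(N / df(t))` with the natural logarithm; zero exactly when a
#' term occurs in every document. Terms absent from the field's vocabulary
#' yield `NA` so the caller can decide how to treat out-of-vocabulary input
#' (vectorizers drop such terms).
#'
#' @param term Character vector of terms.
#' @param stats A `field_stats` object.
#' @return Numeric vector of idf values (`NA` for unknown terms).
#' @export
idf <- function(term, stats) {
  stopifnot(inherits(stats, "field_stats"))
  d <- stats$df[term]
  unname(log(stats$N / as.numeric(d)))
}

#' Body-field term weight
#'
#' The practical retrieval-engine weighting used for document bodies: a
#' square-root norm on term frequency, a squared smoothed idf factor
#' `(1 + log(N / (df + 1)))^2`, and `1/sqrt(document length)` length
#' normalization. Factors that rescale a whole vector uniformly (query norm,
#' coordination) are omitted because they cancel in the cosine.
#'
#' @param term Character vector of terms.
#' @param tf Positive integer term frequencies (recycled against `term`).
#' @param stats Body `field_stats`.
#' @param doc_id Document whose length normalizes the weight.
#' @return Numeric weights (`NA` for out-of-vocabulary terms).
#' @export
body_weight <- function(term, tf, stats, doc_id) {
  stopifnot(inherits(stats, "field_stats"), stats$field == "body")
  if (any(tf < 1)) stop("tf must be >= 1", call. = FALSE)
  len <- stats$doc_length[doc_id]
  if (is.na(len)) stop("unknown doc_id: ", doc_id, call. = FALSE)
  d <- as.numeric(stats$df[term])
  idf_sq <- 1 + log(stats$N / (d + 1))
  unname(sqrt(tf) * idf_sq^2 / sqrt(as.numeric(len)))
}

#' Title-space tf-idf vector of a single title
#'
#' Title term frequency is binary: a term contributes once no matter how often
#' it repeats, with weight `idf(t) = log(N / df(t))`. Terms removed by the
#' `min_df` floor get no entry.
#'
#' @param title Raw title text (or a one-row corpus tibble).
#' @param stats Title `field_stats` built with the `min_df` floor.
#' @return Tibble with columns `term`, `weight`, sorted by term.
#' @export
title_vector <- function(title, stats) {
  stopifnot(inherits(stats, "field_stats"), stats$field == "title")
  if (is.data.frame(title)) title <- title$title[1]
  toks <- unique(tokenize(title, stats$stopwords)[[1]])
  toks <- sort(toks[toks %in% names(stats$df)])
  w <- idf(toks, stats)
  keep <- !is.na(w) & w > 0
  tibble::tibble(term = toks[keep], weight = w[keep])
}

#' Body-space tf-idf vector of a free-text query
#'
#' The query representation used to retrieve the doc vector: one entry per
#' distinct in-vocabulary token, weight `tf * log(N / df)`. Out-of-vocabulary
#' tokens are dropped; if nothing survives the input is uncovered and the
#' result is empty. Terms present in every document carry idf 0 and are
#' likewise dropped (sparse vectors store no zero entries).
#'
#' @param text Raw text (a length-1 character) or a pre-tokenized character
#'   vector of normalized tokens.
#' @param stats Body `field_stats`.
#' @param tokenized Set `TRUE` when `text` is already a token vector.
#' @return Tibble with columns `term`, `weight`, sorted by term.
#' @export
query_vector <- function(text, stats, tokenized = FALSE) {
  stopifnot(inherits(stats, "field_stats"), stats$field == "body")
  toks <- if (tokenized) as.character(text) else tokenize(text, stats$stopwords)[[1]]
  if (length(toks) == 0L) return(tibble::tibble(term = character(0), weight = numeric(0)))
  tab <- table(toks)
  terms <- names(tab)
  keep <- terms %in% names(stats$df)
  terms <- terms[keep]
  tf <- as.numeric(tab[keep])
  w <- tf * idf(terms, stats)
  pos <- !is.na(w) & w > 0
  out <- tibble::tibble(term = terms[pos], weight = w[pos])
  out[order(out$term), ]
}
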