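#' Default English stopword list
#'
#' Returns the stopword list shipped with the package (one lowercase term per
#' line). Shipping a fixed list keeps tokenization reproducible independent of
#' any external library version.
#'
#' @param path Optional path to a custom stopword file (one term per line).
#' @return Character vector of lowercase stopwords.
#' @export
#' @examples
#' head(default_stopwords())
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "tesar")
  }
  if (!file.exists(path)) stop("stopword file not found: ", path, call. = FALSE)
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(words)
  unique(words[nzchar(words)])
}

#' Tokenize raw text
#'
#' Normalizes and splits text the way the indexing pipeline expects: accents
#' are stripped (after Unicode composition), text is lowercased, any run of
#' non-alphanumeric characters acts as a separator (so "heart-attack" yields
#' two tokens), tokens consisting entirely of digits are dropped, and
#' stopwords are removed. Mixed alphanumeric tokens such as "p53" are kept —
#' identifiers of that shape carry signal in scientific text. Token order is
#' preserved.
#'
#' @param text Character vector of raw texts (`NA` is treated as empty).
#' @param stopwords Character vector of stopwords to drop.
#' @return A list with one character vector of tokens per input text.
#' @export
#' @examples
#' tokenize("The Heart-Attack of 2015", stopwords = c("the", "of"))
tokenize <- function(text, stopwords = default_stopwords()) {
  if (length(text) == 0L) return(list())
  text <- as.character(text)
  text[is.na(text)] <- ""
  x <- stringi::stri_trans_nfc(text)
  x <- stringi::stri_trans_general(x, "Any-Latin; Latin-ASCII")
  x <- stringi::stri_trans_tolower(x)
  toks <- stringi::stri_split_regex(x, "[^a-z0-9]+", omit_empty = TRUE)
  lapply(toks, function(tk) {
    if (length(tk) == 0L) return(character(0))
    tk[!stringi::stri_detect_regex(tk, "^[0-9]+$") & !(tk %in% stopwords)]
  })
}

validate_corpus <- function(corpus) {
  if (!is.data.frame(corpus)) stop("corpus must be a data frame", call. = FALSE)
  need <- c("doc_id", "title", "body")
  missing <- setdiff(need, names(corpus))
  if (length(missing) > 0L) {
    stop("corpus is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  corpus <- tibble::as_tibble(corpus[need])
  corpus$doc_id <- as.character(corpus$doc_id)
  corpus$title <- ifelse(is.na(corpus$title), "", as.character(corpus$title))
  corpus$body <- ifelse(is.na(corpus$body), "", as.character(corpus$body))
  if (anyNA(corpus$doc_id) || any(!nzchar(corpus$doc_id))) {
    stop("every document needs a non-empty doc_id", call. = FALSE)
  }
  dup <- unique(corpus$doc_id[duplicated(corpus$doc_id)])
  if (length(dup) > 0L) {
    stop("duplicate doc_id in corpus: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  corpus
}

#' Read a corpus of documents
#'
#' A corpus is a tibble with columns `doc_id`, `title`, `body`; file order is
#' preserved and duplicate identifiers are rejected. Two plain-text formats
#' are supported: JSON lines (one object per line with exactly those keys)
#' and TSV (header row `doc_id`, `title`, `body`; embedded tabs/newlines are
#' not representable).
#'
#' @param path File path.
#' @param format `"jsonl"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @return A tibble with columns `doc_id`, `title`, `body`.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "tab", "txt")) "tsv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- nzchar(trimws(lines))
    records <- vector("list", sum(keep))
    k <- 0L
    for (i in seq_along(lines)) {
      if (!keep[i]) next
      rec <- tryCatch(
        jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
        error = function(e) {
          stop("parse error on line ", i, " of ", path, ": ",
               conditionMessage(e), call. = FALSE)
        }
      )
      if (!is.list(rec) || !all(c("doc_id", "title", "body") %in% names(rec))) {
        stop("parse error on line ", i, " of ", path,
             ": record must have keys doc_id, title, body", call. = FALSE)
      }
      k <- k + 1L
      records[[k]] <- tibble::tibble(
        doc_id = as.character(rec$doc_id)[1],
        title = as.character(rec$title)[1],
        body = as.character(rec$body)[1]
      )
    }
    corpus <- dplyr::bind_rows(records)
  } else {
    corpus <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                              progress = FALSE, na = character())
    probs <- readr::problems(corpus)
    if (nrow(probs) > 0L) {
      stop("parse error on line ", probs$row[1] + 1L, " of ", path, ": ",
           probs$expected[1], " expected", call. = FALSE)
    }
  }
  validate_corpus(corpus)
}

#' Write a corpus to disk
#'
#' @param corpus Corpus tibble (`doc_id`, `title`, `body`).
#' @param path Output file path.
#' @param format `"jsonl"` or `"tsv"`. The TSV form cannot hold embedded tabs
#'   or newlines and errors if any field contains one.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  corpus <- validate_corpus(corpus)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(list(doc_id = corpus$doc_id[i], title = corpus$title[i],
                            body = corpus$body[i]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    bad <- vapply(corpus, function(col) any(grepl("[\t\r\n]", col)), logical(1))
    if (any(bad)) {
      stop("tsv corpus cannot contain tabs or newlines (column(s): ",
           paste(names(corpus)[bad], collapse = ", "), ")", call. = FALSE)
    }
    readr::write_tsv(corpus, path, progress = FALSE)
  }
  invisible(path)
}

#' Title vocabulary under a document-frequency floor
#'
#' Title terms occurring in fewer than `min_df` distinct document titles are
#' disregarded; the body field is never filtered this way. The default floor
#' of 3 documents mirrors standard practice for noisy title vocabulary.
#'
#' @param corpus Corpus tibble.
#' @param min_df Minimum number of distinct documents a title term must occur
#'   in (default 3).
#' @param stopwords Stopword list used during tokenization.
#' @return Sorted character vector of retained title terms.
#' @export
title_vocabulary <- function(corpus, min_df = 3L, stopwords = default_stopwords()) {
  stats <- build_field_statistics(corpus, "title", min_df = min_df,
                                  stopwords = stopwords)
  names(stats$df)
}
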