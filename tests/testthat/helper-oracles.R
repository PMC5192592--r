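# Small fixtures and independent brute-force oracles used across the suite.
# Oracles use explicit dense loops (no sparse algebra) so they stay independent
# of the implementation paths they check.

mk_corpus <- function(ids, titles, bodies) {
  tibble::tibble(doc_id = ids, title = titles, body = bodies)
}

# random small title+body corpus over fixed token pools
rand_corpus <- function(n_docs, seed) {
  withr::with_seed(seed, {
    pool_body <- sprintf("w%02d", 1:40)
    pool_title <- sprintf("k%02d", 1:12)
    bodies <- vapply(seq_len(n_docs), function(i) {
      paste(sample(pool_body, sample(6:18, 1), replace = TRUE), collapse = " ")
    }, character(1))
    titles <- vapply(seq_len(n_docs), function(i) {
      paste(sample(pool_title, sample(2:5, 1), replace = TRUE), collapse = " ")
    }, character(1))
    mk_corpus(sprintf("d%03d", seq_len(n_docs)), titles, bodies)
  })
}

rand_query <- function(seed, n_tokens = NULL) {
  withr::with_seed(seed, {
    k <- if (is.null(n_tokens)) sample(1:4, 1) else n_tokens
    paste(sample(sprintf("w%02d", 1:40), k, replace = TRUE), collapse = " ")
  })
}

# dense body weight matrix (docs x terms), explicit recount
oracle_body_matrix <- function(corpus, stopwords = default_stopwords()) {
  toks <- tokenize(corpus$body, stopwords)
  n <- nrow(corpus)
  vocab <- sort(unique(unlist(toks)))
  df <- vapply(vocab, function(t) {
    sum(vapply(toks, function(tk) t %in% tk, logical(1)))
  }, numeric(1))
  W <- matrix(0, n, length(vocab), dimnames = list(corpus$doc_id, vocab))
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    len <- length(tk)
    for (t in unique(tk)) {
      tf <- sum(tk == t)
      W[i, t] <- sqrt(tf) * (1 + log(n / (df[[t]] + 1)))^2 / sqrt(len)
    }
  }
  W
}

# dense untruncated doc vector: cosine of the query against every body
oracle_doc_vector <- function(corpus, query, stopwords = default_stopwords()) {
  W <- oracle_body_matrix(corpus, stopwords)
  n <- nrow(corpus)
  toks <- tokenize(corpus$body, stopwords)
  qt <- tokenize(query, stopwords)[[1]]
  qt <- qt[qt %in% colnames(W)]
  if (length(qt) == 0L) return(numeric(0))
  tab <- table(qt)
  terms <- names(tab)
  df <- vapply(terms, function(t) {
    sum(vapply(toks, function(tk) t %in% tk, logical(1)))
  }, numeric(1))
  qw <- as.numeric(tab) * log(n / df)
  keep <- qw > 0
  terms <- terms[keep]
  qw <- qw[keep]
  if (length(terms) == 0L) return(numeric(0))
  qn <- sqrt(sum(qw^2))
  scores <- vapply(seq_len(n), function(i) {
    dn <- sqrt(sum(W[i, ]^2))
    if (dn == 0) return(0)
    sum(W[i, terms] * qw) / (dn * qn)
  }, numeric(1))
  names(scores) <- corpus$doc_id
  scores[scores > 0]
}

# dense title matrix (title terms x docs), binary tf, Eq.-1-style idf
oracle_title_matrix <- function(corpus, stopwords = default_stopwords(),
                                min_df = 3L) {
  toks <- lapply(tokenize(corpus$title, stopwords), unique)
  n <- nrow(corpus)
  all_terms <- sort(unique(unlist(toks)))
  df <- vapply(all_terms, function(t) {
    sum(vapply(toks, function(tk) t %in% tk, logical(1)))
  }, numeric(1))
  vocab <- all_terms[df >= min_df]
  Cm <- matrix(0, length(vocab), n, dimnames = list(vocab, corpus$doc_id))
  for (i in seq_len(n)) {
    for (t in intersect(toks[[i]], vocab)) {
      w <- log(n / df[[t]])
      if (w > 0) Cm[t, i] <- w
    }
  }
  Cm
}

# dense title-space transform of a doc vector given a dense title matrix
oracle_tesa <- function(Cm, dv) {
  if (nrow(dv) == 0L || nrow(Cm) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  out <- vapply(rownames(Cm), function(term) {
    sum(Cm[term, dv$doc_id] * dv$weight)
  }, numeric(1))
  out[out > 0]
}

# mid-rank + hand-rolled Pearson oracle for the Spearman coefficient
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# doc-vector tibble -> named numeric for comparisons
dv_named <- function(dv) stats::setNames(dv$weight, dv$doc_id)

# trivariate normal draws via chol (for CI coverage experiments)
rmvnorm3 <- function(n, R) {
  matrix(stats::rnorm(n * 3), n, 3) %*% chol(R)
}
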