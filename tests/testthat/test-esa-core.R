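test_that("index construction is deterministic and postings mirror incidence", {
  one <- mk_corpus("d1", "t", "a b")
  idx1 <- build_semantic_index(one, stopwords = character(), min_df = 1)
  expect_equal(dim(idx1$B), c(1L, 2L))
  expect_equal(length(idx1$B@x), 2L)

  corpus <- rand_corpus(10, seed = 5)
  a <- build_semantic_index(corpus)
  b <- build_semantic_index(corpus)
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  # posting-list lengths equal document frequencies from a brute-force scan
  toks <- tokenize(corpus$body, default_stopwords())
  for (term in names(a$body_stats$df)) {
    incidence <- sum(vapply(toks, function(tk) term %in% tk, logical(1)))
    expect_equal(unname(Matrix::colSums(a$B[, term, drop = FALSE] > 0)),
                 incidence)
    expect_equal(unname(a$body_stats$df[term]), as.integer(incidence))
  }
})

test_that("a document's own body retrieves it with weight one under orthogonal vocabularies", {
  # uniform within-document tf and df, so the query- and document-side
  # weighting schemes are proportional and the self-cosine is exactly 1
  corpus <- mk_corpus(
    sprintf("d%d", 1:3), rep("t", 3),
    c("aa bb", "cc dd", "ee ff ee ff")
  )
  idx <- build_semantic_index(corpus, stopwords = character(), min_df = 1)
  dv <- doc_vector(idx, "aa bb")
  expect_equal(dv$doc_id, "d1")
  expect_equal(dv$weight, 1, ignore_attr = TRUE)
})

test_that("doc vectors match the dense cosine oracle and truncate to the global top", {
  corpus <- rand_corpus(20, seed = 9)
  idx <- build_semantic_index(corpus)
  query <- rand_query(31, n_tokens = 3)
  full <- doc_vector(idx, query, M = nrow(corpus))
  oracle <- oracle_doc_vector(corpus, query)
  got <- dv_named(full)
  expect_equal(got[sort(names(got))], oracle[sort(names(oracle))],
               tolerance = 1e-10)
  expect_true(all(full$weight > 0 & full$weight <= 1 + 1e-12))

  top5 <- doc_vector(idx, query, M = 5)
  oracle_top5 <- utils::head(sort(oracle, decreasing = TRUE), 5)
  expect_equal(sort(dv_named(top5)), sort(oracle_top5), tolerance = 1e-10)

  # M larger than the number of matching documents is a no-op
  expect_equal(doc_vector(idx, query, M = 10000), full)
})

test_that("doc vectors are invariant to uniform query scaling", {
  corpus <- rand_corpus(15, seed = 21)
  idx <- build_semantic_index(corpus)
  q1 <- doc_vector(idx, "w01 w05")
  q2 <- doc_vector(idx, "w01 w05 w01 w05")  # doubles every tf
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("truncation keeps the M largest weights with deterministic ties", {
  dv <- tibble::tibble(doc_id = c("c", "a", "b"), weight = c(0.5, 0.5, 0.5))
  kept <- truncate_doc_vector(dv, 2)
  expect_equal(kept$doc_id, c("a", "b"))

  expect_equal(truncate_doc_vector(dv, 7)$doc_id, c("a", "b", "c"))

  withr::with_seed(13, {
    big <- tibble::tibble(doc_id = sprintf("d%03d", 1:100),
                          weight = sample(rep(runif(40), length.out = 100)))
  })
  kept10 <- truncate_doc_vector(big, 10)
  o <- order(-big$weight, big$doc_id)   # sort-and-slice oracle
  expect_equal(kept10$doc_id, big$doc_id[o][1:10])

  # monotone subsets in M
  corpus <- rand_corpus(25, seed = 3)
  idx <- build_semantic_index(corpus)
  dv_full <- doc_vector(idx, "w02 w07 w11", M = 25)
  for (m in c(1, 3, 7, 12)) {
    small <- doc_vector(idx, "w02 w07 w11", M = m)
    larger <- doc_vector(idx, "w02 w07 w11", M = m + 5)
    expect_true(all(small$doc_id %in% larger$doc_id))
    expect_true(all(larger$doc_id %in% dv_full$doc_id))
  }
})

test_that("a persisted index reloads with identical scoring behaviour", {
  corpus <- rand_corpus(12, seed = 17)
  idx <- build_semantic_index(corpus)
  dir <- withr::local_tempdir()
  write_semantic_index(idx, dir)
  back <- read_semantic_index(dir)
  q <- "w03 w09"
  expect_equal(doc_vector(back, q), doc_vector(idx, q), tolerance = 1e-12)
  expect_equal(tesa_vector(back, doc_vector(back, q)),
               tesa_vector(idx, doc_vector(idx, q)), tolerance = 1e-12)
  expect_error(read_semantic_index(file.path(dir, "nope")), "meta.json")
})
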