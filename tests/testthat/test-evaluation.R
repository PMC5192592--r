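ref_file <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("reference datasets load, validate their scale, and carry sd", {
  path <- ref_file(c("label_1\tlabel_2\tscore",
                     "heart\tattack\t1200", "heart\tlung\t400", "a\tb\t0"))
  d <- load_reference(path, scale = c(0, 1600))
  expect_equal(nrow(d), 3L)
  expect_equal(attr(d, "scale"), c(0, 1600))

  with_sd <- ref_file(c("label_1,label_2,score,sd",
                        "x,y,5,1.5", "x,z,2,0.5"), ext = ".csv")
  d2 <- load_reference(with_sd, scale = c(1, 10))
  expect_equal(d2$sd, c(1.5, 0.5))

  out_of_scale <- ref_file(c("label_1\tlabel_2\tscore", "x\ty\t12"))
  expect_error(load_reference(out_of_scale, scale = c(1, 10)), "scale")

  missing_col <- ref_file(c("label_1\tscore", "x\t5"))
  expect_error(load_reference(missing_col, scale = c(1, 10)), "label_2")

  not_numeric <- ref_file(c("label_1\tlabel_2\tscore", "x\ty\thigh"))
  expect_error(load_reference(not_numeric, scale = c(1, 10)), "non-numeric")
})

test_that("the rank correlation is exact on monotone lists and handles ties by mid-rank", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_rho(x, x * 2 + 1), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # invariance under strictly monotone transforms
  expect_equal(spearman_rho(x, exp(x)), 1)
  withr::with_seed(55, {
    a <- sample(1:5, 12, replace = TRUE)
    b <- sample(1:5, 12, replace = TRUE)
  })
  expect_equal(spearman_rho(a, b), oracle_spearman(a, b), tolerance = 1e-12)
  expect_error(spearman_rho(1, 2), "at least 2")
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
})

test_that("evaluation excludes uncovered pairs and reports label recall", {
  corpus <- rand_corpus(25, seed = 19)
  idx <- build_semantic_index(corpus, min_df = 2)
  reference <- tibble::tibble(
    label_1 = c("w01", "w02", "w03", "w04", "w05", "qqzz"),
    label_2 = c("w06", "w07", "w08", "w09", "w10", "w01"),
    score = c(900, 150, 620, 480, 1100, 700)
  )
  attr(reference, "name") <- "handmade"
  ev <- evaluate_benchmark(reference, idx, "esa", M = 25)
  expect_equal(ev$n_used, 5L)                 # the qqzz pair is excluded
  expect_equal(ev$recall, 10 / 11)            # 10 of 11 distinct labels covered
  # hand-traced expectation through the dense oracle pipeline
  want <- vapply(1:5, function(i) {
    o1 <- oracle_doc_vector(corpus, reference$label_1[i])
    o2 <- oracle_doc_vector(corpus, reference$label_2[i])
    sh <- intersect(names(o1), names(o2))
    sum(o1[sh] * o2[sh]) / (sqrt(sum(o1^2)) * sqrt(sum(o2^2)))
  }, numeric(1))
  expect_equal(ev$rho, oracle_spearman(want, reference$score[1:5]),
               tolerance = 1e-10)
  expect_equal(glance(ev)$rho, ev$rho)
  expect_equal(nrow(tidy(ev)), 6L)

  none <- tibble::tibble(label_1 = "zz1", label_2 = "zz2", score = 5)
  expect_error(evaluate_benchmark(none, idx, "esa"), "fewer than 2")
})

test_that("the agreement sweep filters by sd threshold with undefined tails", {
  corpus <- rand_corpus(25, seed = 19)
  idx <- build_semantic_index(corpus, min_df = 2)
  reference <- tibble::tibble(
    label_1 = c("w01", "w02", "w03", "w04"),
    label_2 = c("w06", "w07", "w08", "w09"),
    score = c(900, 150, 620, 480),
    sd = c(100, 100, 300, 300)
  )
  sw <- iaa_sweep(reference, idx, "esa", thresholds = c(400, 300, 100, 50), M = 25)
  expect_equal(sw$n_pairs, c(4L, 4L, 2L, 0L))   # two sd strata, hand count
  full <- evaluate_benchmark(reference, idx, "esa", M = 25)
  expect_equal(sw$rho[1], full$rho)             # threshold above max sd
  expect_true(is.na(sw$rho[4]))                 # threshold below min sd
  no_sd <- reference[, 1:3]
  expect_error(iaa_sweep(no_sd, idx, "esa", thresholds = 1), "sd column")
})

test_that("the dependent-correlation interval is centred and dependency-aware", {
  eq <- compare_correlations(0.5, 0.5, 0.3, 50)
  expect_equal(eq$estimate, 0)
  expect_equal(eq$ci_low, -eq$ci_high)
  expect_false(eq$significant)

  # the interval always contains the point estimate (realizable triples)
  withr::with_seed(77, {
    for (i in 1:50) {
      x <- rnorm(20)
      y <- x * runif(1, -1, 1) + rnorm(20)
      z <- x * runif(1, -1, 1) + rnorm(20)
      cc <- compare_correlations(cor(x, z), cor(y, z), cor(x, y),
                                 sample(10:200, 1))
      expect_true(cc$ci_low <= cc$estimate && cc$estimate <= cc$ci_high)
    }
  })

  # stronger dependence between the score lists narrows the interval
  wide <- compare_correlations(0.6, 0.4, 0.0, 60)
  narrow <- compare_correlations(0.6, 0.4, 0.9, 60)
  expect_lt(narrow$ci_high - narrow$ci_low, wide$ci_high - wide$ci_low)

  expect_error(compare_correlations(1, 0.5, 0.3, 50), "\\(-1, 1\\)")
  expect_error(compare_correlations(0.5, 0.4, 0.3, 3), "at least 4")
})

test_that("method comparison runs on the common covered subset", {
  cfg <- synthetic_config(n_topics = 4, docs_per_topic = 25, seed = 3)
  idx <- build_semantic_index(generate_corpus(cfg))
  ref <- generate_reference(cfg, n_pairs = 40)
  cmp <- compare_methods(ref, idx)
  td <- tidy(cmp)
  expect_equal(td$method_1, "tesa")
  expect_true(td$ci_low <= td$estimate && td$estimate <= td$ci_high)
  expect_lte(cmp$n_used, nrow(ref))
})

test_that("correlation rises when planted annotator noise is removed", {
  diffs_tesa <- c()
  diffs_esa <- c()
  for (s in 42:44) {
    cfg <- synthetic_config(seed = s)
    idx <- build_semantic_index(generate_corpus(cfg))
    noisy <- generate_reference(cfg)
    clean <- generate_reference(cfg, jitter = FALSE)
    diffs_tesa <- c(diffs_tesa,
                    evaluate_benchmark(clean, idx, "tesa")$rho -
                      evaluate_benchmark(noisy, idx, "tesa")$rho)
    diffs_esa <- c(diffs_esa,
                   evaluate_benchmark(clean, idx, "esa")$rho -
                     evaluate_benchmark(noisy, idx, "esa")$rho)
  }
  expect_gt(mean(diffs_tesa), 0)
  expect_gt(mean(diffs_esa), 0)
})

test_that("excluding low-agreement pairs raises the correlation on average", {
  gains <- c()
  for (s in 42:44) {
    cfg <- synthetic_config(seed = s)
    idx <- build_semantic_index(generate_corpus(cfg))
    ref <- generate_reference(cfg, n_pairs = 300)
    for (m in c("tesa", "esa")) {
      sw <- iaa_sweep(ref, idx, m, thresholds = c(Inf, 220))
      gains <- c(gains, sw$rho[2] - sw$rho[1])
    }
  }
  expect_gt(mean(gains), 0)
})
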