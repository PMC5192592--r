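#' Cosine similarity of two sparse weight vectors
#'
#' Vectors are two-column data frames: a key column (`term` or `doc_id`)
#' followed by `weight`. Both arguments must live in the same space — the key
#' columns must carry the same name — otherwise an error is raised. If either
#' vector is empty or has zero norm the similarity is 0.
#'
#' @param a,b Sparse vectors as tibbles (key column, then `weight`).
#' @return A number in `[0, 1]` for non-negative weights.
#' @export
#' @examples
#' a <- tibble::tibble(term = c("x", "y"), weight = c(1, 2))
#' b <- tibble::tibble(term = c("x", "y"), weight = c(2, 1))
#' cosine_similarity(a, b)  # 0.8
cosine_similarity <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  key_a <- names(a)[1]
  key_b <- names(b)[1]
  if (!identical(key_a, key_b)) {
    stop("vectors live in different spaces (keys '", key_a, "' vs '", key_b,
         "')", call. = FALSE)
  }
  na <- sqrt(sum(a$weight^2))
  nb <- sqrt(sum(b$weight^2))
  if (na == 0 || nb == 0) return(0)
  m <- match(a[[1]], b[[1]])
  hit <- !is.na(m)
  if (!any(hit)) return(0)
  sum(a$weight[hit] * b$weight[m[hit]]) / (na * nb)
}

representation <- function(index, text, method, M) {
  dv <- doc_vector(index, text, M = M)
  if (method == "esa") dv else tesa_vector(index, dv)
}

#' Relatedness of two free-text inputs
#'
#' Runs the full three-step pipeline for both inputs — body-space query
#' vector, truncated doc vector, and (for tESA) the title-space transform —
#' and returns the cosine of the two final representations. An input whose
#' representation is empty is *uncovered*: the score is 0 and the
#' corresponding coverage flag is `FALSE`, so evaluation code can exclude
#' such pairs rather than treat 0 as a judgment.
#'
#' @param index A `semantic_index`.
#' @param input_1,input_2 Raw texts; multi-word inputs are treated as a
#'   single multi-token query.
#' @param method `"tesa"` or `"esa"`.
#' @param M Doc-vector truncation bound (default 10000).
#' @return One-row tibble: `input_1`, `input_2`, `method`, `score`,
#'   `covered_1`, `covered_2`.
#' @export
relatedness <- function(index, input_1, input_2, method = c("tesa", "esa"),
                        M = 10000L) {
  method <- match.arg(method)
  v1 <- representation(index, input_1, method, M)
  v2 <- representation(index, input_2, method, M)
  covered_1 <- nrow(v1) > 0L
  covered_2 <- nrow(v2) > 0L
  score <- if (covered_1 && covered_2) cosine_similarity(v1, v2) else 0
  tibble::tibble(
    input_1 = input_1, input_2 = input_2, method = method,
    score = score, covered_1 = covered_1, covered_2 = covered_2
  )
}

#' Score a table of input pairs
#'
#' Vectorized form of [relatedness()]: each distinct label is represented
#' once (the pipeline is run per label, not per pair) and every row of
#' `pairs` receives a score and coverage flags.
#'
#' @param pairs Data frame whose first two columns (or columns `label_1`,
#'   `label_2`) hold the input texts.
#' @param index A `semantic_index`.
#' @param method `"tesa"` or `"esa"`.
#' @param M Doc-vector truncation bound.
#' @return The input tibble with `score` (the system score), `covered_1`,
#'   `covered_2` and `method` columns appended; an existing `score` column in
#'   the input (e.g. a reference dataset's consensus mean) is preserved as
#'   `human_score`.
#' @export
score_pairs <- function(pairs, index, method = c("tesa", "esa"), M = 10000L) {
  method <- match.arg(method)
  stopifnot(is.data.frame(pairs))
  if (all(c("label_1", "label_2") %in% names(pairs))) {
    l1 <- as.character(pairs$label_1)
    l2 <- as.character(pairs$label_2)
  } else {
    if (ncol(pairs) < 2L) stop("pairs needs two label columns", call. = FALSE)
    l1 <- as.character(pairs[[1]])
    l2 <- as.character(pairs[[2]])
  }
  labels <- unique(c(l1, l2))
  reps <- lapply(labels, function(lab) representation(index, lab, method, M))
  names(reps) <- labels
  covered <- vapply(reps, nrow, integer(1)) > 0L
  score <- vapply(seq_along(l1), function(i) {
    if (covered[[l1[i]]] && covered[[l2[i]]]) {
      cosine_similarity(reps[[l1[i]]], reps[[l2[i]]])
    } else 0
  }, numeric(1))
  out <- tibble::as_tibble(pairs)
  if ("score" %in% names(out)) {
    # keep a reference dataset's own consensus column out of the way
    names(out)[names(out) == "score"] <- "human_score"
  }
  out$score <- score
  out$covered_1 <- unname(covered[l1])
  out$covered_2 <- unname(covered[l2])
  out$method <- method
  out
}
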