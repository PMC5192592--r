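#' Load a reference relatedness dataset
#'
#' Reference datasets are delimited tables of human-rated concept pairs:
#' columns `label_1`, `label_2`, `score` (the annotator consensus mean) and
#' optionally `sd` (per-pair standard deviation across annotators, a proxy
#' for inter-annotator agreement). Scores outside the declared rating scale
#' and negative standard deviations are rejected.
#'
#' @param path TSV or CSV file (delimiter guessed from the extension).
#' @param scale Length-2 numeric: the rating scale bounds, e.g. `c(0, 1600)`.
#' @param name Optional dataset name (stored as an attribute).
#' @return Tibble with columns `label_1`, `label_2`, `score` and, when
#'   present in the file, `sd`; attributes `scale` and `name`.
#' @export
load_reference <- function(path, scale = c(0, 1600), name = NULL) {
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  stopifnot(is.numeric(scale), length(scale) == 2L, scale[1] < scale[2])
  ext <- tolower(tools::file_ext(path))
  reader <- if (ext == "csv") readr::read_csv else readr::read_tsv
  df <- reader(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  need <- c("label_1", "label_2", "score")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("reference dataset is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    label_1 = as.character(df$label_1),
    label_2 = as.character(df$label_2),
    score = suppressWarnings(as.numeric(df$score))
  )
  if (anyNA(out$score)) {
    stop("non-numeric score in reference dataset (row ",
         which(is.na(out$score))[1], ")", call. = FALSE)
  }
  if (any(out$score < scale[1] | out$score > scale[2])) {
    stop("score outside the declared scale [", scale[1], ", ", scale[2],
         "] (row ", which(out$score < scale[1] | out$score > scale[2])[1], ")",
         call. = FALSE)
  }
  if ("sd" %in% names(df)) {
    out$sd <- suppressWarnings(as.numeric(df$sd))
    if (anyNA(out$sd)) {
      stop("non-numeric sd in reference dataset (row ",
           which(is.na(out$sd))[1], ")", call. = FALSE)
    }
    if (any(out$sd < 0)) stop("negative sd in reference dataset", call. = FALSE)
  }
  attr(out, "scale") <- as.numeric(scale)
  attr(out, "name") <- name %||% tools::file_path_sans_ext(basename(path))
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive their average rank, the
#' standard convention). Errors, rather than returning `NA`, when fewer than
#' two observations are available or either argument has zero rank variance,
#' since a correlation is undefined there.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The coefficient, in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined: zero rank variance", call. = FALSE)
  }
  stats::cor(rx, ry)
}

fisher_ci <- function(rho, n, conf = 0.95) {
  if (n < 4L || abs(rho) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(rho)
  half <- stats::qnorm((1 + conf) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Evaluate a relatedness method against a reference dataset
#'
#' Scores every pair, computes Spearman's rank correlation between the
#' system scores and the human consensus means over the pairs where *both*
#' inputs are covered (uncovered pairs are excluded rather than scored 0 —
#' coverage is reported separately as recall), and reports recall as the
#' fraction of the dataset's distinct labels that receive a non-empty
#' representation.
#'
#' @param reference Reference tibble (see [load_reference()] /
#'   [generate_reference()]).
#' @param index A `semantic_index`.
#' @param method `"tesa"` or `"esa"`.
#' @param M Doc-vector truncation bound.
#' @param conf Confidence level for the Fisher-z interval on the coefficient.
#' @return A `tesa_eval` object; see [glance.tesa_eval()] for the one-row
#'   summary and [tidy.tesa_eval()] for per-pair scores.
#' @export
evaluate_benchmark <- function(reference, index, method = c("tesa", "esa"),
                               M = 10000L, conf = 0.95) {
  method <- match.arg(method)
  stopifnot(is.data.frame(reference),
            all(c("label_1", "label_2", "score") %in% names(reference)))
  scored <- score_pairs(reference, index, method = method, M = M)
  labels <- c(scored$label_1, scored$label_2)
  covered <- c(scored$covered_1, scored$covered_2)
  cov_by_label <- tapply(covered, labels, any)
  recall <- mean(cov_by_label)
  usable <- scored$covered_1 & scored$covered_2
  n_used <- sum(usable)
  if (n_used < 2L) {
    stop("fewer than 2 pairs with both inputs covered; correlation undefined",
         call. = FALSE)
  }
  rho <- spearman_rho(scored$score[usable], reference$score[usable])
  ci <- fisher_ci(rho, n_used, conf)
  structure(
    list(
      method = method, M = as.integer(M),
      dataset = attr(reference, "name") %||% "reference",
      rho = rho, ci_low = ci[1], ci_high = ci[2], conf = conf,
      n_used = n_used, n_pairs = nrow(scored), recall = recall,
      scores = scored
    ),
    class = "tesa_eval"
  )
}

#' @export
print.tesa_eval <- function(x, ...) {
  cat("<tesa_eval> ", x$method, " on '", x$dataset, "'\n", sep = "")
  cat(sprintf("  Spearman rho: %.4f  (%d%% CI %.4f..%.4f)\n",
              x$rho, round(100 * x$conf), x$ci_low, x$ci_high))
  cat(sprintf("  pairs used:   %d / %d\n", x$n_used, x$n_pairs))
  cat(sprintf("  recall:       %.4f\n", x$recall))
  invisible(x)
}

#' Per-pair scores of an evaluation
#'
#' @param x A `tesa_eval` object.
#' @param ... Unused.
#' @return Tibble of per-pair system scores and coverage flags.
#' @export
tidy.tesa_eval <- function(x, ...) x$scores

#' One-row summary of an evaluation
#'
#' @param x A `tesa_eval` object.
#' @param ... Unused.
#' @return One-row tibble: method, dataset, rho with its Fisher-z interval,
#'   pairs used, pair count, recall.
#' @export
glance.tesa_eval <- function(x, ...) {
  tibble::tibble(
    method = x$method, dataset = x$dataset, M = x$M,
    rho = x$rho, ci_low = x$ci_low, ci_high = x$ci_high,
    n_used = x$n_used, n_pairs = x$n_pairs, recall = x$recall
  )
}

#' Agreement-stratified evaluation sweep
#'
#' Re-evaluates a method on nested subsets of a reference dataset obtained by
#' lowering a per-pair standard-deviation threshold, i.e. progressively
#' excluding the pairs human annotators agreed on least. Thresholds that
#' leave fewer than two usable pairs yield an `NA` coefficient rather than
#' an error.
#'
#' @param reference Reference tibble with an `sd` column.
#' @param index A `semantic_index`.
#' @param method `"tesa"` or `"esa"`.
#' @param thresholds Numeric vector of sd cutoffs (typically descending).
#' @param M Doc-vector truncation bound.
#' @return A tibble (class `tesa_iaa_sweep`): `threshold`, `rho`, `n_used`,
#'   `recall`, `method`.
#' @export
iaa_sweep <- function(reference, index, method = c("tesa", "esa"),
                      thresholds, M = 10000L) {
  method <- match.arg(method)
  if (!"sd" %in% names(reference)) {
    stop("reference dataset has no sd column; cannot stratify by agreement",
         call. = FALSE)
  }
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1L)
  scored <- score_pairs(reference, index, method = method, M = M)
  usable <- scored$covered_1 & scored$covered_2
  rows <- lapply(thresholds, function(thr) {
    sel <- reference$sd <= thr
    use <- sel & usable
    rho <- if (sum(use) >= 2L) {
      tryCatch(spearman_rho(scored$score[use], reference$score[use]),
               error = function(e) NA_real_)
    } else NA_real_
    labels <- c(scored$label_1[sel], scored$label_2[sel])
    covered <- c(scored$covered_1[sel], scored$covered_2[sel])
    recall <- if (length(labels) > 0L) mean(tapply(covered, labels, any)) else NA_real_
    tibble::tibble(threshold = thr, rho = rho, n_used = sum(use),
                   n_pairs = sum(sel), recall = recall, method = method)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tesa_iaa_sweep", class(out))
  out
}

#' Plot an agreement-stratified sweep
#'
#' Correlation as a function of the decreasing standard-deviation threshold;
#' the x axis is reversed so agreement increases to the right.
#'
#' @param object A `tesa_iaa_sweep` tibble (possibly several methods bound
#'   together).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tesa_iaa_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$threshold, y = .data$rho,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "sd threshold (agreement increases →)",
                  y = "Spearman rho", colour = "method") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation: system scores against human consensus
#'
#' @param object A `tesa_eval` object.
#' @param ... Unused.
#' @return A ggplot object (pairs with an uncovered input are greyed out).
#' @export
autoplot.tesa_eval <- function(object, ...) {
  d <- object$scores
  d$covered <- d$covered_1 & d$covered_2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$human_score, y = .data$score,
                                  colour = .data$covered)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8",
                                            `FALSE` = "grey70")) +
    ggplot2::labs(
      x = "human consensus score", y = paste(object$method, "score"),
      title = sprintf("%s on '%s': Spearman rho = %.3f",
                      object$method, object$dataset, object$rho)
    ) +
    ggplot2::theme_minimal()
}

#' Confidence interval for a difference of dependent overlapping correlations
#'
#' Two methods evaluated against the same human ratings yield two correlation
#' coefficients that share a variable; comparing them needs a
#' dependency-adjusted interval. This is the modified asymptotic construction
#' of Zou (2007): per-coefficient Fisher-z limits are combined with the
#' correlation between the two coefficient estimates, which is driven by
#' `rho_12`, the correlation between the two methods' score lists.
#'
#' @param rho_1,rho_2 The two coefficients sharing a variable, each in
#'   `(-1, 1)`.
#' @param rho_12 Correlation between the two score lists themselves, computed
#'   on the same pair subset as `rho_1` and `rho_2`.
#' @param n Number of observations behind the coefficients (at least 4).
#' @param conf Confidence level (default 0.95).
#' @return A `cor_comparison` object with the interval for `rho_1 - rho_2`
#'   and a `significant` flag (interval excludes 0).
#' @export
compare_correlations <- function(rho_1, rho_2, rho_12, n, conf = 0.95) {
  stopifnot(length(rho_1) == 1L, length(rho_2) == 1L, length(rho_12) == 1L)
  if (anyNA(c(rho_1, rho_2, rho_12, n))) stop("degenerate input: NA", call. = FALSE)
  if (abs(rho_1) >= 1 || abs(rho_2) >= 1 || abs(rho_12) > 1) {
    stop("correlations must lie in (-1, 1)", call. = FALSE)
  }
  if (n < 4L) stop("n must be at least 4", call. = FALSE)
  if (conf <= 0 || conf >= 1) stop("conf must be in (0, 1)", call. = FALSE)

  l1 <- fisher_ci(rho_1, n, conf)[1]; u1 <- fisher_ci(rho_1, n, conf)[2]
  l2 <- fisher_ci(rho_2, n, conf)[1]; u2 <- fisher_ci(rho_2, n, conf)[2]
  # correlation between the two sample coefficients (Zou 2007)
  num <- (rho_12 - 0.5 * rho_1 * rho_2) *
    (1 - rho_1^2 - rho_2^2 - rho_12^2) + rho_12^3
  den <- (1 - rho_1^2) * (1 - rho_2^2)
  # clamp: nearly-degenerate triples can push the ratio out of [-1, 1]
  corr_r1r2 <- max(-1, min(1, num / den))
  est <- rho_1 - rho_2
  lo <- est - sqrt((rho_1 - l1)^2 + (u2 - rho_2)^2 -
                     2 * corr_r1r2 * (rho_1 - l1) * (u2 - rho_2))
  hi <- est + sqrt((u1 - rho_1)^2 + (rho_2 - l2)^2 -
                     2 * corr_r1r2 * (u1 - rho_1) * (rho_2 - l2))
  structure(
    list(rho_1 = rho_1, rho_2 = rho_2, rho_12 = rho_12, n = as.integer(n),
         conf = conf, estimate = est, ci_low = lo, ci_high = hi,
         significant = lo > 0 || hi < 0),
    class = "cor_comparison"
  )
}

#' @export
print.cor_comparison <- function(x, ...) {
  cat("<cor_comparison> rho_1 - rho_2\n")
  cat(sprintf("  rho_1 = %.4f, rho_2 = %.4f, rho_12 = %.4f, n = %d\n",
              x$rho_1, x$rho_2, x$rho_12, x$n))
  cat(sprintf("  difference: %.4f  (%d%% CI %.4f..%.4f)  %s\n",
              x$estimate, round(100 * x$conf), x$ci_low, x$ci_high,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' @rdname compare_correlations
#' @param x A `cor_comparison` object.
#' @param ... Unused.
#' @export
tidy.cor_comparison <- function(x, ...) {
  tibble::tibble(
    rho_1 = x$rho_1, rho_2 = x$rho_2, rho_12 = x$rho_12, n = x$n,
    estimate = x$estimate, conf = x$conf,
    ci_low = x$ci_low, ci_high = x$ci_high, significant = x$significant
  )
}

#' Compare two relatedness methods on one reference dataset
#'
#' Evaluates both methods, restricts to the pairs covered under both,
#' recomputes both coefficients on that common subset, measures the
#' correlation between the two score lists (`rho_12`, Spearman by default for
#' consistency with the compared coefficients) and builds the
#' dependent-overlapping-correlations interval for their difference.
#'
#' @param reference Reference tibble.
#' @param index A `semantic_index`.
#' @param methods Length-2 character, default `c("tesa", "esa")`.
#' @param M Doc-vector truncation bound.
#' @param conf Confidence level.
#' @param coef `"spearman"` (default) or `"pearson"` — the coefficient fed
#'   into the interval machinery.
#' @return A `tesa_method_comparison` object; `tidy()` gives a one-row
#'   summary.
#' @export
compare_methods <- function(reference, index, methods = c("tesa", "esa"),
                            M = 10000L, conf = 0.95,
                            coef = c("spearman", "pearson")) {
  coef <- match.arg(coef)
  stopifnot(length(methods) == 2L)
  s1 <- score_pairs(reference, index, method = methods[1], M = M)
  s2 <- score_pairs(reference, index, method = methods[2], M = M)
  usable <- s1$covered_1 & s1$covered_2 & s2$covered_1 & s2$covered_2
  if (sum(usable) < 4L) {
    stop("fewer than 4 pairs covered under both methods", call. = FALSE)
  }
  cc <- function(x, y) {
    if (coef == "spearman") spearman_rho(x, y) else stats::cor(x, y)
  }
  rho_1 <- cc(s1$score[usable], reference$score[usable])
  rho_2 <- cc(s2$score[usable], reference$score[usable])
  rho_12 <- cc(s1$score[usable], s2$score[usable])
  comparison <- compare_correlations(rho_1, rho_2, rho_12, sum(usable), conf)
  structure(
    list(methods = methods, coef = coef, n_used = sum(usable),
         comparison = comparison,
         dataset = attr(reference, "name") %||% "reference"),
    class = "tesa_method_comparison"
  )
}

#' @export
print.tesa_method_comparison <- function(x, ...) {
  cat("<tesa_method_comparison> ", x$methods[1], " vs ", x$methods[2],
      " on '", x$dataset, "' (", x$coef, ", n = ", x$n_used, ")\n", sep = "")
  print(x$comparison)
  invisible(x)
}

#' @rdname compare_methods
#' @param x A `tesa_method_comparison` object.
#' @param ... Unused.
#' @export
tidy.tesa_method_comparison <- function(x, ...) {
  out <- tidy(x$comparison)
  tibble::add_column(out,
                     method_1 = x$methods[1], method_2 = x$methods[2],
                     dataset = x$dataset, coef = x$coef, .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
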