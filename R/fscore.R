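split_classes <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels))
    stop("feature matrix has no labels; F-score needs both classes",
         call. = FALSE)
  pos <- fm$x[fm$labels == 1L, , drop = FALSE]
  neg <- fm$x[fm$labels == -1L, , drop = FALSE]
  if (nrow(pos) < 2L || nrow(neg) < 2L)
    stop(sprintf(
      "insufficient class size for F-score: %d positive, %d negative (need >= 2 each)",
      nrow(pos), nrow(neg)), call. = FALSE)
  list(pos = pos, neg = neg)
}

#' F-score of every feature
#'
#' The filter F-score of feature i is the squared separation of the class
#' means from the overall mean, divided by the pooled (n-1 denominator)
#' within-class variances:
#' \deqn{F_i = \frac{(\bar x_i^{(+)} - \bar x_i)^2 + (\bar x_i^{(-)} -
#'   \bar x_i)^2}{\frac{1}{n_+-1}\sum_k (x_{k,i}^{(+)} - \bar x_i^{(+)})^2
#'   + \frac{1}{n_--1}\sum_k (x_{k,i}^{(-)} - \bar x_i^{(-)})^2}}
#' Larger scores indicate better discrimination. A feature constant in
#' both classes (zero denominator) scores 0.
#'
#' @param fm A labeled [feature_matrix()] with at least 2 instances per
#'   class.
#' @return Named numeric vector of nonnegative F-scores.
#' @export
f_score_all <- function(fm) {
  cl <- split_classes(fm)
  mu <- colMeans(fm$x)
  mu_p <- colMeans(cl$pos)
  mu_n <- colMeans(cl$neg)
  num <- (mu_p - mu)^2 + (mu_n - mu)^2
  den <- apply(cl$pos, 2L, var) + apply(cl$neg, 2L, var)
  f <- ifelse(den == 0, 0, num / den)
  stats::setNames(as.numeric(f), colnames(fm$x))
}

#' F-score of a single feature
#'
#' @inheritParams f_score_all
#' @param feature_index Column index (or name) of the feature.
#' @return Nonnegative F-score.
#' @export
f_score <- function(fm, feature_index) {
  f_score_all(fm)[[feature_index]]
}

#' Rank features by F-score and select the top subset
#'
#' Features are ranked by descending F-score; ties are broken by canonical
#' (column) order, so of two identical columns the earlier one wins.
#'
#' @inheritParams f_score_all
#' @param m Number of features to select (1 <= m <= ncol).
#' @return Object of class `fscore_ranking`: `scores` (named, input
#'   order), `ranking` (column indices, best first), `selected` (m feature
#'   names), `n_pos`, `n_neg`, `m`.
#' @export
rank_and_select <- function(fm, m) {
  scores <- f_score_all(fm)
  p <- length(scores)
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m > p)
    stop(sprintf("m must be in [1, %d], got %s", p, format(m)),
         call. = FALSE)
  m <- as.integer(m)
  ranking <- order(-scores, seq_len(p))
  structure(list(
    scores = scores,
    ranking = ranking,
    selected = names(scores)[ranking[seq_len(m)]],
    n_pos = sum(fm$labels == 1L),
    n_neg = sum(fm$labels == -1L),
    m = m
  ), class = "fscore_ranking")
}

#' @export
print.fscore_ranking <- function(x, ...) {
  cat(sprintf("<fscore_ranking> %d features, top %d selected (n+=%d, n-=%d)\n",
              length(x$scores), x$m, x$n_pos, x$n_neg))
  top <- x$ranking[seq_len(min(5L, x$m))]
  for (i in top)
    cat(sprintf("  %-18s F = %.4g\n", names(x$scores)[i], x$scores[i]))
  invisible(x)
}

#' Write an F-score ranking report as TSV
#'
#' Columns: feature, group (when the features are the canonical 65),
#' f_score, rank, selected.
#'
#' @param ranking An [rank_and_select()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  stopifnot(inherits(ranking, "fscore_ranking"))
  nm <- names(ranking$scores)
  grp <- if (identical(nm, feature_names())) feature_groups() else
    rep(NA_character_, length(nm))
  rank_pos <- match(seq_along(nm), ranking$ranking)
  df <- data.frame(
    feature = nm, group = grp, f_score = ranking$scores, rank = rank_pos,
    selected = nm %in% ranking$selected,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  df <- df[order(df$rank), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
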