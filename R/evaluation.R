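#' Confusion matrix from truth and prediction labels
#'
#' @param truth,pred Integer vectors over \{+1, -1\}.
#' @return Object of class `confusion_matrix` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred),
            all(truth %in% c(1L, -1L)), all(pred %in% c(1L, -1L)))
  structure(list(
    tp = sum(truth == 1L & pred == 1L),
    fp = sum(truth == -1L & pred == 1L),
    tn = sum(truth == -1L & pred == -1L),
    fn = sum(truth == 1L & pred == -1L)
  ), class = "confusion_matrix")
}

#' Geometric mean of sensitivity and specificity
#'
#' `Gm = sqrt(SE * SP)`, the headline metric for imbalanced
#' classification: it is high only when both classes are predicted well.
#'
#' @param se,sp Sensitivity and specificity in percent.
#' @return Gm in percent.
#' @export
gm_percent <- function(se, sp) sqrt(se * sp)

#' Classification metrics from a confusion matrix
#'
#' `SE = 100 TP / (TP + FN)`, `SP = 100 TN / (TN + FP)`,
#' `Acc = 100 (TP + TN) / total`, `Gm = sqrt(SE * SP)`. Both classes must
#' be present among the tested samples.
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `metrics_report` with `se`, `sp`, `gm`, `acc`
#'   (percentages).
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0L)
    stop("undefined metric: no positive samples tested", call. = FALSE)
  if (cm$tn + cm$fp == 0L)
    stop("undefined metric: no negative samples tested", call. = FALSE)
  se <- 100 * cm$tp / (cm$tp + cm$fn)
  sp <- 100 * cm$tn / (cm$tn + cm$fp)
  structure(list(
    se = se, sp = sp, gm = gm_percent(se, sp),
    acc = 100 * (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SE=%.2f%% SP=%.2f%% Gm=%.2f%% Acc=%.2f%%\n",
              x$se, x$sp, x$gm, x$acc))
  invisible(x)
}

#' Outer 3-fold stratified cross-validation of the ensemble pipeline
#'
#' The labeled data is split into three folds preserving the class ratio
#' (per-class fold sizes differ by at most 1). For each fold, the full
#' pipeline — feature selection, scaling, negative partitioning and
#' ensemble training — is fitted on the other two folds, then evaluated on
#' the held-out fold under every requested aggregation mode. The final
#' report is the arithmetic mean of the three fold-level reports.
#'
#' @inheritParams train_ensemble
#' @param aggregation Character vector of aggregation modes to evaluate.
#' @param n_folds Number of outer folds (default 3).
#' @param ... Passed through to [train_ensemble()] (grids, `inner_folds`,
#'   `centroid`).
#' @return Object of class `cv_report`: `mean` and `folds`, each a named
#'   list (one entry per aggregation mode) of [compute_metrics()]
#'   reports, plus the fold assignment.
#' @export
outer_3fold_cv <- function(fm, k = 3L, select_m = NULL,
                           aggregation = c("mean_distance",
                                           "majority_vote"),
                           n_folds = 3L, seed = 1L, ...) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  aggregation <- match.arg(aggregation, several.ok = TRUE)
  if (min(table(fm$labels)) < n_folds)
    stop(sprintf("need at least %d samples per class", n_folds),
         call. = FALSE)
  assign <- make_stratified_folds(fm$labels, n_folds, seed)
  fold_reports <- lapply(seq_len(n_folds), function(f) {
    tr <- assign != f
    fm_train <- feature_matrix(fm$x[tr, , drop = FALSE],
                               labels = fm$labels[tr], ids = fm$ids[tr])
    fm_test <- feature_matrix(fm$x[!tr, , drop = FALSE],
                              labels = fm$labels[!tr], ids = fm$ids[!tr])
    model <- train_ensemble(fm_train, k = k, select_m = select_m,
                            seed = seed + f, ...)
    reps <- lapply(aggregation, function(mode) {
      pred <- predict(model, fm_test, aggregation = mode)
      compute_metrics(confusion_matrix(fm_test$labels, pred))
    })
    stats::setNames(reps, aggregation)
  })
  mean_report <- lapply(aggregation, function(mode) {
    avg <- function(field) mean(vapply(fold_reports,
                                       function(r) r[[mode]][[field]],
                                       numeric(1)))
    structure(list(se = avg("se"), sp = avg("sp"), gm = avg("gm"),
                   acc = avg("acc")), class = "metrics_report")
  })
  structure(list(
    mean = stats::setNames(mean_report, aggregation),
    folds = fold_reports,
    fold_assignment = assign,
    seed = as.integer(seed)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds (seed %d)\n", length(x$folds), x$seed))
  for (mode in names(x$mean)) {
    cat(sprintf("  %-14s ", mode))
    print(x$mean[[mode]])
  }
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' One row per (fold, aggregation) plus `mean` rows; metrics in percent.
#'
#' @param report A [outer_3fold_cv()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_tsv <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  rows <- list()
  for (f in seq_along(report$folds)) {
    for (mode in names(report$folds[[f]])) {
      r <- report$folds[[f]][[mode]]
      rows[[length(rows) + 1L]] <- data.frame(
        fold = as.character(f), aggregation = mode,
        SE = round(r$se, 2), SP = round(r$sp, 2),
        Gm = round(r$gm, 2), Acc = round(r$acc, 2))
    }
  }
  for (mode in names(report$mean)) {
    r <- report$mean[[mode]]
    rows[[length(rows) + 1L]] <- data.frame(
      fold = "mean", aggregation = mode,
      SE = round(r$se, 2), SP = round(r$sp, 2),
      Gm = round(r$gm, 2), Acc = round(r$acc, 2))
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
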