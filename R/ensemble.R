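fit_scaling <- function(x) {
  list(min = apply(x, 2L, min), max = apply(x, 2L, max))
}

apply_scaling <- function(x, scaling) {
  rng <- scaling$max - scaling$min
  rng[rng == 0] <- 1  # constant training feature maps to -1; harmless
  scaled <- sweep(sweep(x, 2L, scaling$min, "-"), 2L, rng, "/") * 2 - 1
  scaled
}

#' Partition the negative class by distance to the positive centroid
#'
#' Negatives are sorted ascending by Euclidean distance (in the scaled
#' feature space) to the positive-class centroid and cut into `k`
#' contiguous blocks of near-equal size (sizes differ by at most 1, the
#' first blocks take the remainder). Block 1 is the "closer set" — the
#' negatives most similar to real precursors, which are the hardest to
#' separate.
#'
#' @param fm A labeled [feature_matrix()].
#' @param k Number of partitions (1 <= k <= number of negatives).
#' @return List of `k` integer vectors of row indices into `fm`.
#' @export
partition_negatives <- function(fm, k) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  neg_idx <- which(fm$labels == -1L)
  if (k < 1L || k > length(neg_idx))
    stop(sprintf("k must be in [1, %d], got %s", length(neg_idx), format(k)),
         call. = FALSE)
  k <- as.integer(k)
  scaling <- fit_scaling(fm$x)
  xs <- apply_scaling(fm$x, scaling)
  pos_centroid <- colMeans(xs[fm$labels == 1L, , drop = FALSE])
  d <- sqrt(colSums((t(xs[neg_idx, , drop = FALSE]) - pos_centroid)^2))
  ordered <- neg_idx[order(d)]
  sizes <- rep(length(ordered) %/% k, k)
  extra <- length(ordered) %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) ordered[starts[i]:ends[i]])
}

make_stratified_folds <- function(labels, n_folds, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# Inner cross-validated grid search over (cost, gamma), selecting by Gm.
# Ties go to the earliest grid row (grid order: gamma varies fastest).
tune_rbf <- function(x, y, cost_grid, gamma_grid, inner_folds, seed) {
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n_min <- min(table(y))
  folds <- min(inner_folds, n_min)
  if (folds < 2L) {
    return(list(cost = cost_grid[1L], gamma = gamma_grid[1L], gm = NA_real_))
  }
  assign <- make_stratified_folds(as.integer(as.character(y)), folds, seed)
  gms <- vapply(seq_len(nrow(grid)), function(g) {
    fold_gm <- vapply(seq_len(folds), function(f) {
      tr <- assign != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], scale = FALSE,
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g])
      pred <- as.integer(as.character(predict(fit, x[!tr, , drop = FALSE])))
      truth <- as.integer(as.character(y[!tr]))
      se <- 100 * sum(pred == 1L & truth == 1L) / max(1L, sum(truth == 1L))
      sp <- 100 * sum(pred == -1L & truth == -1L) / max(1L, sum(truth == -1L))
      sqrt(se * sp)
    }, numeric(1))
    mean(fold_gm)
  }, numeric(1))
  best <- which.max(gms)
  list(cost = grid$cost[best], gamma = grid$gamma[best], gm = gms[best])
}

#' Train an imbalance-aware SVM ensemble
#'
#' Splits the negative class into `k` distance-ordered partitions
#' ([partition_negatives()]) and trains one RBF-kernel SVM per partition
#' on (all positives + that partition), with per-submodel hyperparameters
#' chosen by inner cross-validated grid search maximizing the geometric
#' mean of sensitivity and specificity. Feature values are min-max scaled
#' to [-1, 1] using the training data only; the same scaling (and feature
#' selection, if requested) is stored in the model and reapplied at
#' prediction time. The centroid of each sub-training set is stored for
#' mean-distance dispatch.
#'
#' @param fm A labeled [feature_matrix()].
#' @param k Number of negative partitions (must not exceed the
#'   negative:positive size ratio).
#' @param select_m Optional number of features to retain by F-score
#'   ranking on the training data (`NULL` keeps all features).
#' @param aggregation Default aggregation mode stored in the model:
#'   `"mean_distance"` or `"majority_vote"` (prediction can override).
#' @param cost_grid,gamma_grid Log-spaced hyperparameter grids.
#' @param inner_folds Inner CV folds for the grid search (default 5).
#' @param seed Integer seed driving inner fold assignment.
#' @param centroid `"subset"` (positives + partition, the default) or
#'   `"negatives"` (partition only) for the stored centroids.
#' @return Object of class `hairpin_ensemble`.
#' @export
train_ensemble <- function(fm, k = 3L, select_m = NULL,
                           aggregation = c("mean_distance", "majority_vote"),
                           cost_grid = 2^seq(-5, 15, by = 4),
                           gamma_grid = 2^seq(-15, 1, by = 4),
                           inner_folds = 5L, seed = 1L,
                           centroid = c("subset", "negatives")) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  aggregation <- match.arg(aggregation)
  centroid <- match.arg(centroid)
  n_pos <- sum(fm$labels == 1L)
  n_neg <- sum(fm$labels == -1L)
  if (n_pos == 0L || n_neg == 0L)
    stop("training requires both classes", call. = FALSE)
  k_max <- max(1L, n_neg %/% n_pos)
  if (k < 1L || k > k_max)
    stop(sprintf("k must be in [1, %d] (negative:positive ratio), got %s",
                 k_max, format(k)), call. = FALSE)
  k <- as.integer(k)

  selected <- colnames(fm$x)
  if (!is.null(select_m)) {
    ranking <- rank_and_select(fm, select_m)
    selected <- sort(match(ranking$selected, colnames(fm$x)))
    selected <- colnames(fm$x)[selected]  # keep canonical column order
  }
  x_sel <- fm$x[, selected, drop = FALSE]
  fm_sel <- feature_matrix(x_sel, labels = fm$labels, ids = fm$ids)
  scaling <- fit_scaling(x_sel)
  xs <- apply_scaling(x_sel, scaling)

  parts <- partition_negatives(fm_sel, k)
  pos_idx <- which(fm$labels == 1L)
  submodels <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- c(pos_idx, parts[[i]])
    if (length(unique(fm$labels[idx])) < 2L)
      stop("degenerate single-class training subset", call. = FALSE)
    xi <- xs[idx, , drop = FALSE]
    yi <- factor(fm$labels[idx], levels = c(-1L, 1L))
    tuned <- tune_rbf(xi, yi, cost_grid, gamma_grid, inner_folds,
                      seed = seed + i)
    fit <- e1071::svm(xi, yi, scale = FALSE, kernel = "radial",
                      cost = tuned$cost, gamma = tuned$gamma)
    cen_idx <- if (centroid == "subset") idx else parts[[i]]
    submodels[[i]] <- list(
      fit = fit, cost = tuned$cost, gamma = tuned$gamma,
      inner_gm = tuned$gm, partition_index = i,
      centroid = colMeans(xs[cen_idx, , drop = FALSE])
    )
  }
  structure(list(
    k = k, submodels = submodels, scaling = scaling,
    selected = selected, aggregation = aggregation,
    centroid_mode = centroid, seed = as.integer(seed),
    schema_version = 1L
  ), class = "hairpin_ensemble")
}

#' @export
print.hairpin_ensemble <- function(x, ...) {
  cat(sprintf(
    "<hairpin_ensemble> k=%d, %d features, default aggregation: %s\n",
    x$k, length(x$selected), x$aggregation))
  invisible(x)
}

#' Resolve a majority vote with the latter-half tie rule
#'
#' Votes are ordered by partition index (1 = the "closer set" of negatives
#' nearest the positive centroid). A strict majority wins. On an exact tie
#' (even k), the majority among the latter half of submodels (partition
#' index > k/2) decides, because submodels trained on closer sets are
#' known to vote positive too eagerly; if the latter half is itself tied,
#' the submodel with the largest partition index decides.
#'
#' @param votes Integer vector over \{+1, -1\}, ordered by partition
#'   index.
#' @return +1 or -1.
#' @export
combine_votes <- function(votes) {
  stopifnot(length(votes) >= 1L, all(votes %in% c(1L, -1L)))
  s <- sum(votes)
  if (s != 0L) return(if (s > 0L) 1L else -1L)
  latter <- votes[(length(votes) %/% 2L + 1L):length(votes)]
  s2 <- sum(latter)
  if (s2 != 0L) return(if (s2 > 0L) 1L else -1L)
  votes[length(votes)]
}

prepare_newdata <- function(model, newdata) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else
    as.matrix(newdata)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, names(newdata)))
  missing <- setdiff(model$selected, colnames(x))
  if (length(missing) > 0L)
    stop("newdata lacks model features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  apply_scaling(x[, model$selected, drop = FALSE], model$scaling)
}

submodel_votes <- function(model, xs) {
  vapply(model$submodels, function(sm) {
    as.integer(as.character(predict(sm$fit, xs)))
  }, integer(nrow(xs)))
}

#' Predict by majority vote over all submodels
#'
#' Every submodel classifies every sample; ties are resolved by
#' [combine_votes()].
#'
#' @param model A trained [train_ensemble()] model.
#' @param newdata A [feature_matrix()], numeric matrix, or single named
#'   vector.
#' @param details If `TRUE`, also return the per-submodel vote matrix.
#' @return Integer labels (+1/-1); with `details`, a list with `label`
#'   and `votes`.
#' @export
predict_majority <- function(model, newdata, details = FALSE) {
  xs <- prepare_newdata(model, newdata)
  votes <- submodel_votes(model, xs)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(xs))
  labels <- apply(votes, 1L, combine_votes)
  if (details) list(label = labels, votes = votes) else labels
}

#' Predict by mean-distance dispatch
#'
#' Each sample is classified exactly once, by the submodel whose
#' training-set centroid is nearest in the scaled feature space
#' (Euclidean); equidistant centroids resolve to the lowest partition
#' index.
#'
#' @inheritParams predict_majority
#' @return Integer labels; with `details`, a list with `label` and
#'   `dispatch` (the 1-based submodel index per sample).
#' @export
predict_mean_distance <- function(model, newdata, details = FALSE) {
  xs <- prepare_newdata(model, newdata)
  centroids <- do.call(rbind, lapply(model$submodels, `[[`, "centroid"))
  d <- vapply(seq_len(model$k), function(i) {
    sqrt(rowSums(sweep(xs, 2L, centroids[i, ], "-")^2))
  }, numeric(nrow(xs)))
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(xs))
  dispatch <- apply(d, 1L, which.min)  # which.min takes the lowest index on ties
  labels <- integer(nrow(xs))
  for (i in unique(dispatch)) {
    rows <- which(dispatch == i)
    labels[rows] <- as.integer(as.character(
      predict(model$submodels[[i]]$fit, xs[rows, , drop = FALSE])))
  }
  if (details) list(label = labels, dispatch = dispatch) else labels
}

#' @export
predict.hairpin_ensemble <- function(object, newdata,
                                     aggregation = NULL, details = FALSE,
                                     ...) {
  aggregation <- if (is.null(aggregation)) object$aggregation else
    match.arg(aggregation, c("mean_distance", "majority_vote"))
  if (aggregation == "mean_distance")
    predict_mean_distance(object, newdata, details = details)
  else
    predict_majority(object, newdata, details = details)
}

#' Save / load a trained ensemble
#'
#' The archive is a single RDS file containing the scaling parameters,
#' selected feature names, k, aggregation mode, per-submodel
#' hyperparameters and support data, and a schema version.
#'
#' @param model A trained [train_ensemble()] model.
#' @param path Archive path.
#' @return `path` invisibly (`save_ensemble`); the model
#'   (`load_ensemble`).
#' @export
save_ensemble <- function(model, path) {
  stopifnot(inherits(model, "hairpin_ensemble"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hairpin_ensemble"))
    stop("not a hairpin_ensemble archive: ", path, call. = FALSE)
  model
}
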