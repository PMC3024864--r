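small_grid <- list(cost_grid = 2^c(0, 4), gamma_grid = 2^c(-4, 0),
                   inner_folds = 3L)

train_small <- function(fm, k, ...) {
  do.call(train_ensemble, c(list(fm = fm, k = k, seed = 5), small_grid,
                            list(...)))
}

test_that("partition_negatives sorts by distance and cuts near-equal blocks", {
  # one feature; negatives at known distances from the positive centroid
  x <- matrix(c(0, 0, 1, 2, 3, 4, 5), ncol = 1,
              dimnames = list(NULL, "f01"))
  fm <- feature_matrix(x, labels = c(1L, 1L, rep(-1L, 5)))
  parts <- partition_negatives(fm, 2L)
  expect_identical(lengths(parts), c(3L, 2L))
  expect_identical(parts[[1]], 3:5)  # negatives at distances 1,2,3
  expect_identical(parts[[2]], 6:7)

  expect_identical(lengths(partition_negatives(fm, 1L)), 5L)
  expect_error(partition_negatives(fm, 6L), "k must be")
})

test_that("near-equal split arithmetic matches the 5428-negative case", {
  sizes <- function(n, k) {
    s <- rep(n %/% k, k); s[seq_len(n %% k)] <- s[seq_len(n %% k)] + 1L; s
  }
  x <- matrix(rnorm(5428 + 697), ncol = 1, dimnames = list(NULL, "f01"))
  fm <- feature_matrix(x, labels = rep(c(1L, -1L), c(697L, 5428L)))
  parts <- partition_negatives(fm, 3L)
  expect_identical(unname(lengths(parts)), c(1810L, 1809L, 1809L))
  expect_identical(unname(lengths(parts)), sizes(5428L, 3L))
})

test_that("the majority-vote tie cascade follows the latter-half rule", {
  expect_identical(combine_votes(c(1L, 1L, -1L)), 1L)
  expect_identical(combine_votes(c(-1L, -1L, 1L)), -1L)
  # k = 2 tie: the non-closer-set submodel decides
  expect_identical(combine_votes(c(1L, -1L)), -1L)
  expect_identical(combine_votes(c(-1L, 1L)), 1L)
  # k = 4 overall tie, latter half (3,4) also tied: submodel 4 decides
  expect_identical(combine_votes(c(1L, -1L, 1L, -1L)), -1L)
  expect_identical(combine_votes(c(-1L, 1L, -1L, 1L)), 1L)
  # k = 4 overall tie, latter half unanimous
  expect_identical(combine_votes(c(1L, 1L, -1L, -1L)), -1L)
  expect_identical(combine_votes(c(-1L, -1L, 1L, 1L)), 1L)
})

test_that("k = 1 majority vote and mean distance coincide", {
  fm <- make_separable_table(12, 14, seed = 2, n_features = 6,
                             n_informative = 3)
  model <- train_small(fm, k = 1L)
  expect_identical(model$k, 1L)
  mv <- predict_majority(model, fm)
  md <- predict_mean_distance(model, fm)
  expect_identical(mv, md)
})

test_that("a separable table is fit perfectly and deterministically", {
  fm <- make_separable_table(12, 40, seed = 3, n_features = 10,
                             n_informative = 4)
  model <- train_small(fm, k = 3L)
  pred <- predict(model, fm, aggregation = "majority_vote")
  m <- compute_metrics(confusion_matrix(fm$labels, pred))
  expect_equal(m$gm, 100)
  pred_md <- predict(model, fm, aggregation = "mean_distance")
  expect_equal(compute_metrics(confusion_matrix(fm$labels, pred_md))$gm, 100)

  held <- make_separable_table(8, 20, seed = 77, n_features = 10,
                               n_informative = 4)
  model2 <- train_small(fm, k = 3L)
  expect_identical(predict(model2, held), predict(model, held))
})

test_that("mean-distance dispatch sends each sample to exactly one submodel", {
  fm <- make_separable_table(12, 40, seed = 4, n_features = 8,
                             n_informative = 3)
  model <- train_small(fm, k = 3L)
  res <- predict_mean_distance(model, fm, details = TRUE)
  expect_length(res$dispatch, nrow(fm$x))
  expect_true(all(res$dispatch %in% 1:3))
  expect_identical(sum(tabulate(res$dispatch, 3L)), nrow(fm$x))
  # a sample placed exactly at a centroid is dispatched to that submodel
  at_centroid <- model$submodels[[2]]$centroid
  # invert the scaling to express the centroid in raw feature units
  rng <- model$scaling$max - model$scaling$min
  raw <- (at_centroid + 1) / 2 * rng + model$scaling$min
  one <- matrix(raw, nrow = 1, dimnames = list(NULL, model$selected))
  expect_identical(predict_mean_distance(model, one, details = TRUE)$dispatch,
                   2L)
})

test_that("training validates k against the class ratio and labels", {
  fm <- make_separable_table(10, 30, seed = 6, n_features = 5,
                             n_informative = 2)
  expect_error(train_small(fm, k = 5L), "k must be in \\[1, 3\\]")
  unlabeled <- feature_matrix(fm$x)
  expect_error(train_ensemble(unlabeled, k = 1L), "label")
})

test_that("feature selection inside training restricts the model surface", {
  fm <- make_separable_table(10, 30, seed = 9, n_features = 12,
                             n_informative = 3)
  model <- train_small(fm, k = 2L, select_m = 3L)
  expect_length(model$selected, 3L)
  expect_true(all(model$selected %in% sprintf("f%02d", 1:3)))
  pred <- predict(model, fm)
  expect_equal(compute_metrics(confusion_matrix(fm$labels, pred))$gm, 100)
})

test_that("serialization round-trips predictions exactly", {
  fm <- make_separable_table(10, 24, seed = 13, n_features = 6,
                             n_informative = 2)
  model <- train_small(fm, k = 2L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(model, path)
  back <- load_ensemble(path)
  expect_identical(predict(back, fm), predict(model, fm))
  expect_identical(back$selected, model$selected)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_ensemble(bad), "not a hairpin_ensemble")
})

test_that("centroids can optionally cover the negative partition only", {
  fm <- make_separable_table(10, 24, seed = 14, n_features = 6,
                             n_informative = 2)
  m_subset <- train_small(fm, k = 2L, centroid = "subset")
  m_neg <- train_small(fm, k = 2L, centroid = "negatives")
  expect_false(isTRUE(all.equal(m_subset$submodels[[1]]$centroid,
                                m_neg$submodels[[1]]$centroid)))
})
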