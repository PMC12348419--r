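test_that("stratified folds are balanced, exhaustive and deterministic", {
  labels <- stats::setNames(rep(c("amino", "sugar"), times = c(26, 28)),
                            sprintf("P%02d", 1:54))
  fold <- stratified_folds(labels, 5, seed = 1)
  expect_setequal(unique(fold), 1:5)
  expect_equal(length(fold), 54L)
  # per-fold class counts within floor/ceil of proportionality
  for (f in 1:5) for (cl in c("amino", "sugar")) {
    cnt <- sum(fold == f & labels == cl)
    size <- sum(labels == cl)
    expect_true(cnt %in% c(floor(size / 5), ceiling(size / 5)))
  }
  # test-set sizes 10-11 on the 54-sample two-class dataset
  expect_true(all(table(fold) %in% c(10L, 11L)))
  # determinism
  expect_identical(fold, stratified_folds(labels, 5, seed = 1))
  expect_false(identical(fold, stratified_folds(labels, 5, seed = 2)))
  # class smaller than n_folds errors
  tiny <- stats::setNames(c(rep("a", 3), rep("b", 10)), paste0("q", 1:13))
  expect_error(stratified_folds(tiny, 5, 1), "fewer than 5")
})

test_that("metrics match the direct-formula oracle", {
  expect_equal(metrics(c("p", "n"), c("p", "n"))$balanced_accuracy, 1)
  # confusion TP=3 FN=1 TN=2 FP=2 with positive class "p"
  y_true <- c(rep("p", 4), rep("n", 4))
  y_pred <- c("p", "p", "p", "n", "p", "p", "n", "n")
  m <- metrics(y_true, y_pred)
  expect_equal(m$balanced_accuracy, 0.625)
  expect_equal(unname(m$f1_per_class["p"]), 2 / 3)
  expect_equal(unname(m$f1_per_class["n"]), 4 / 7)
  expect_equal(m$macro_f1, 13 / 21)
  # constant predictor on balanced truth -> balanced accuracy exactly 1/K
  const <- metrics(rep(c("a", "b"), each = 10), rep("a", 20))
  expect_equal(const$balanced_accuracy, 0.5)
  # zero-division convention: unpredicted class has F1 = 0
  expect_equal(unname(const$f1_per_class["b"]), 0)
  # constant predictor under imbalance still scores exactly 1/K
  imb <- metrics(rep(c("a", "b"), times = c(18, 2)), rep("a", 20))
  expect_equal(imb$balanced_accuracy, 0.5)
  expect_error(metrics(c("a", "b"), "a"), "length")
})

test_that("nested CV yields 25 rows with shared splits across features", {
  b <- blob_matrix(n_per_class = 27, d = 8, sep = 6, seed = 11)
  rep1 <- nested_cv_evaluate(b$fm, b$labels, "svm", master_seed = 3)
  expect_equal(nrow(rep1$rows), 25L)
  expect_equal(sort(unique(rep1$rows$repetition)), 1:5)
  expect_equal(sort(unique(rep1$rows$fold)), 1:5)
  # strong signal: essentially perfect held-out performance
  expect_gte(mean(rep1$rows$balanced_accuracy), 0.95)
  # chosen hyperparameters logged per split
  expect_true(all(rep1$rows$chosen_k >= 1))
  expect_true(all(rep1$rows$chosen_C %in% c(0.1, 1, 10)))

  # identical fold assignments for every feature under one master seed:
  # folds depend only on (labels, seed), asserted directly per repetition
  for (r in 1:5) {
    f1 <- stratified_folds(b$labels, 5, seed = 3L + r)
    f2 <- stratified_folds(b$labels, 5, seed = 3L + r)
    expect_identical(f1, f2)
  }

  # misaligned rows error
  bad <- b$labels
  names(bad)[1] <- "nope"
  expect_error(nested_cv_evaluate(b$fm, bad, "svm", 3), "misaligned")
})

test_that("aggregate_report computes mean and n-1 sd", {
  b <- blob_matrix(n_per_class = 27, d = 8, sep = 6, seed = 11)
  rep1 <- nested_cv_evaluate(b$fm, b$labels, "svm", master_seed = 3)
  agg <- aggregate_report(rep1)
  ba <- rep1$rows$balanced_accuracy
  expect_equal(agg$mean[agg$metric == "balanced_accuracy"], mean(ba))
  expect_equal(agg$sd[agg$metric == "balanced_accuracy"], sd(ba))
  # 25 identical scores -> sd 0
  fake <- rep1
  fake$rows$balanced_accuracy <- 0.8
  expect_equal(aggregate_report(fake)$sd[1], 0)
  # closed form for a {0,1} mixture: 15 ones, 10 zeros
  fake$rows$balanced_accuracy <- rep(c(1, 0), times = c(15, 10))
  expect_equal(aggregate_report(fake)$mean[1], 0.6)
  expect_equal(aggregate_report(fake)$sd[1], sqrt(15 * 10 / 25 / 24))
  empty <- structure(list(rows = NULL), class = "evaluation_report")
  expect_error(aggregate_report(empty), "empty")
})

test_that("report export writes scores TSV and aggregate JSON", {
  b <- blob_matrix(n_per_class = 10, d = 5, sep = 4, seed = 12)
  rep1 <- nested_cv_evaluate(b$fm, b$labels, "svm", master_seed = 1,
                             n_folds = 2L, n_repetitions = 2L)
  dir <- withr::local_tempdir()
  export_report(rep1, dir)
  expect_equal(nrow(read.delim(file.path(dir, "scores.tsv"))), 4L)
  agg <- jsonlite::read_json(file.path(dir, "aggregates.json"))
  expect_equal(agg$model, "svm")
})

test_that("label permutation destroys performance down to chance", {
  b <- blob_matrix(n_per_class = 27, d = 8, sep = 4, seed = 13)
  perm <- b$labels
  set.seed(99)
  names(perm) <- names(b$labels)
  perm[] <- sample(perm)
  rep_perm <- nested_cv_evaluate(b$fm, perm, "svm", master_seed = 5)
  expect_lt(mean(rep_perm$rows$balanced_accuracy), 0.65)
  expect_gt(mean(rep_perm$rows$balanced_accuracy), 0.35)
})
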