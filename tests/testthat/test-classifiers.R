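test_that("variance_filter removes exactly-constant training columns", {
  x <- cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = rep(2.5, 4))
  vf <- variance_filter(x)
  expect_equal(vf$kept, "b")
  # no constant columns -> identity
  x2 <- cbind(a = rnorm(5), b = rnorm(5))
  expect_equal(variance_filter(x2)$kept, c("a", "b"))
  # train-derived mask applies the same columns to test data
  test_x <- cbind(a = rnorm(3), b = rnorm(3), c = rnorm(3))
  expect_equal(colnames(test_x[, vf$kept, drop = FALSE]), "b")
  expect_error(variance_filter(x[, "a", drop = FALSE]), "every feature")
})

test_that("anova_f_scores matches hand and loop oracles", {
  # classes (1,2,3) vs (7,8,9): between-SS 54 / df 1, within-SS 4 / df 4
  # -> F = 54 (value frozen from scipy f_oneway / sklearn f_classif oracles)
  X <- matrix(c(1, 2, 3, 7, 8, 9), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c("a", "b"), each = 3)
  expect_equal(unname(anova_f_scores(X, y)), 54)

  # identical class means -> F = 0
  X0 <- matrix(c(1, 3, 1, 3), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(unname(anova_f_scores(X0, rep(c("a", "b"), each = 2))), 0)

  # random instance vs explicit-loop oracle
  set.seed(2)
  Xr <- matrix(rnorm(40 * 6), 40, 6,
               dimnames = list(NULL, paste0("f", 1:6)))
  yr <- sample(rep(c("a", "b"), each = 20))
  oracle <- vapply(1:6, function(j) {
    v <- Xr[, j]; grand <- mean(v)
    ssb <- ssw <- 0; n <- 40; K <- 2
    for (cl in c("a", "b")) {
      vc <- v[yr == cl]
      ssb <- ssb + length(vc) * (mean(vc) - grand)^2
      ssw <- ssw + sum((vc - mean(vc))^2)
    }
    (ssb / (K - 1)) / (ssw / (n - K))
  }, numeric(1))
  expect_equal(unname(anova_f_scores(Xr, yr)), oracle, tolerance = 1e-9)

  expect_error(anova_f_scores(Xr, c("a", rep("b", 39))), "at least 2")
})

test_that("select_top_k enforces the cap and breaks ties by name", {
  scores <- stats::setNames(c(5, 3, 3, 1), c("d", "b", "a", "c"))
  expect_equal(select_top_k(scores, 2), c("d", "a"))  # tie: a before b
  expect_equal(select_top_k(scores, 4), c("d", "a", "b", "c"))
  expect_error(select_top_k(scores, 5), "out of bounds")
  big <- stats::setNames(runif(300), sprintf("f%03d", 1:300))
  expect_error(select_top_k(big, 201), "out of bounds")
  expect_length(select_top_k(big, 200), 200L)
})

test_that("rbf_gamma implements 1 / (pooled variance * m)", {
  X <- matrix(c(0, 2), 4, 200)  # pooled variance exactly var(c(0,2,...))
  v <- var(as.vector(X))
  expect_equal(rbf_gamma(X), 1 / (v * 200))
  # standardized matrix -> approximately 1/m
  set.seed(3)
  Z <- scale(matrix(rnorm(500), 50, 10))
  expect_equal(rbf_gamma(Z), 1 / (var(as.vector(Z)) * 10), tolerance = 1e-12)
  expect_equal(rbf_gamma(Z) * 10, 1, tolerance = 0.05)
  expect_error(rbf_gamma(matrix(1, 3, 3)), "zero pooled variance")
})

test_that("class_weights implements n / (K * n_i)", {
  expect_equal(unname(class_weights(rep(c("a", "b"), each = 50))), c(1, 1))
  w <- class_weights(rep(c("a", "b"), times = c(20, 40)))
  expect_equal(unname(w), c(1.5, 0.75))
  expect_equal(unname(class_weights(rep(c("a", "b", "c"), each = 10))),
               rep(1, 3))
})

test_that("fit_svm separates synthetic blobs and is deterministic", {
  b <- blob_matrix(n_per_class = 30, d = 10, sep = 4, seed = 4)
  cfg <- svm_config(seed = 7)
  expect_length(cfg$C_grid, 3L)  # three C candidates
  model <- fit_svm(b$fm, b$labels, cfg)
  pred <- predict(model, b$fm)
  expect_equal(metrics(b$labels, pred)$balanced_accuracy, 1.0)
  # identical seed and data -> identical chosen hyperparameters
  model2 <- fit_svm(b$fm, b$labels, cfg)
  expect_identical(model$chosen, model2$chosen)
  expect_lte(length(model$prep$selected), 200L)
  expect_error(fit_svm(b$fm[1:30, ], b$labels[1:30], cfg), "2 classes")
})

test_that("no train/test leakage: preprocessing state ignores test rows", {
  b <- blob_matrix(n_per_class = 20, d = 8, sep = 3, seed = 5)
  train <- b$fm[1:30, ]; test <- b$fm[31:40, ]
  model <- fit_svm(train, b$labels[1:30], svm_config(seed = 1))
  state_before <- model$prep
  mutated <- test
  mutated[, ] <- mutated * 100 + 5
  p1 <- predict(model, test)
  expect_identical(model$prep, state_before)
  # predictions on unrelated data do not alter the stored state either
  invisible(predict(model, mutated))
  expect_identical(model$prep, state_before)
  # preprocessing applied to test uses train-derived center/scale
  expect_equal(model$prep$center,
               colMeans(as.matrix(train)[, model$prep$selected]))
})

test_that("fnn architecture, threshold rule and determinism", {
  cfg <- fnn_config(seed = 3)
  expect_equal(cfg$hidden_sizes, c(512L, 256L, 128L))
  b <- blob_matrix(n_per_class = 20, d = 12, sep = 5, seed = 6)
  model <- fit_fnn(b$fm, b$labels, cfg)
  # layer shapes: input -> 512 -> 256 -> 128 -> 1
  dims <- vapply(model$net, function(l) ncol(l$W), integer(1))
  expect_equal(dims, c(512L, 256L, 128L, 1L))
  # capacity >> task: training accuracy 1.0
  pred <- predict(model, b$fm)
  expect_equal(metrics(b$labels, pred)$balanced_accuracy, 1.0)
  # fixed seed -> identical predictions across two fits
  model2 <- fit_fnn(b$fm, b$labels, cfg)
  expect_equal(attr(predict(model, b$fm), "prob"),
               attr(predict(model2, b$fm), "prob"))
  expect_error(fit_fnn(b$fm, rep("a", 40), cfg), "2 classes")
})

test_that("probability threshold: p = 0.5 is negative, p > 0.5 positive", {
  b <- blob_matrix(n_per_class = 15, d = 5, sep = 4, seed = 8)
  model <- fit_fnn(b$fm, b$labels, fnn_config(epochs = 2L, seed = 1))
  # decision rule applied to the model's own probabilities
  pred <- predict(model, b$fm)
  p <- attr(pred, "prob")
  expect_equal(as.character(pred),
               model$levels[ifelse(p > 0.5, 2L, 1L)])
  # exact boundary: forcing the threshold comparison with p = 0.5
  expect_equal(model$levels[ifelse(0.5 > 0.5, 2L, 1L)], model$levels[1])
  expect_equal(model$levels[ifelse(0.6 > 0.5, 2L, 1L)], model$levels[2])
})

test_that("model save/load round-trips predictions", {
  b <- blob_matrix(n_per_class = 15, d = 6, sep = 4, seed = 9)
  for (fit in list(fit_svm(b$fm, b$labels, svm_config(seed = 2)),
                   fit_fnn(b$fm, b$labels, fnn_config(epochs = 5L,
                                                      seed = 2)))) {
    dir <- withr::local_tempdir()
    save_model(fit, dir)
    expect_true(file.exists(file.path(dir, "model_info.json")))
    back <- load_model(dir)
    expect_equal(as.character(predict(back, b$fm)),
                 as.character(predict(fit, b$fm)))
  }
})

test_that("batch prediction equals per-sample prediction", {
  b <- blob_matrix(n_per_class = 15, d = 6, sep = 4, seed = 10)
  model <- fit_svm(b$fm, b$labels, svm_config(seed = 3))
  batch <- predict(model, b$fm)
  single <- vapply(seq_len(nrow(b$fm)), function(i) {
    predict(model, b$fm[i, , drop = FALSE])
  }, character(1))
  expect_equal(as.character(batch), single)
})
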