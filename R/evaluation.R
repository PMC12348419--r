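#' Stratified fold assignment
#'
#' Shuffles each class with the given seed and deals its members round-robin
#' into folds, so every fold's per-class count is the floor or ceiling of
#' (class size / n_folds). Deterministic given labels and seed.
#'
#' @param labels Named vector: names are sample ids, values class labels.
#'   Each class needs at least `n_folds` members.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Named integer vector of fold numbers (1..n_folds), in the order
#'   of `labels`.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 0L) {
  y <- as.character(labels)
  ids <- names(labels)
  if (is.null(ids)) stop_tp("labels must be named by sample id")
  counts <- table(y)
  if (any(counts < n_folds)) {
    stop_tp("class '", names(counts)[which.min(counts)], "' has fewer than ",
            n_folds, " members")
  }
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    offset <- 0L
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold per class so fold sizes stay balanced
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  stats::setNames(fold, ids)
}

#' Classification metrics for a binary test split
#'
#' Balanced accuracy is the mean of per-class recalls; F1 per class is the
#' harmonic mean of precision and recall with that class treated as
#' positive; macro F1 is the unweighted mean of the per-class F1 scores.
#' Zero-division convention: a class with no predicted positives has
#' precision 0 and F1 0.
#'
#' @param y_true True labels (both classes present).
#' @param y_pred Predicted labels, same length.
#' @return List with `balanced_accuracy`, `f1_per_class` (named) and
#'   `macro_f1`.
#' @export
metrics <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop_tp("y_true and y_pred differ in length")
  }
  classes <- sort(unique(y_true))
  recalls <- f1s <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    recall <- tp / (tp + fn)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recalls[cl] <- recall
    f1s[cl] <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
  }
  list(balanced_accuracy = mean(recalls), f1_per_class = f1s,
       macro_f1 = mean(f1s))
}

#' Nested stratified cross-validation evaluation
#'
#' Five repetitions of a stratified 5-fold cross-validation, reshuffled per
#' repetition with seed `master_seed + repetition`. For each outer fold the
#' model is fitted on the outer-training split — the SVM path runs its inner
#' 5-fold grid search there, the FNN path trains with fixed hyperparameters
#' — and scored on the held-out fold, yielding `n_folds * n_repetitions`
#' test scores. Fold assignments depend only on the labels and the master
#' seed, so every feature dataset evaluated under one master seed sees
#' identical splits. Outlier removal is by design not part of this
#' procedure.
#'
#' @param feature A `feature_matrix`; row names must match the label names.
#' @param labels Named binary label vector covering all rows of `feature`.
#' @param model `"svm"` or `"fnn"`.
#' @param master_seed Integer master seed.
#' @param config Optional [svm_config()] / [fnn_config()]; the seed field is
#'   rederived per repetition.
#' @param n_folds,n_repetitions Protocol shape (defaults 5 and 5).
#' @return An `evaluation_report`: list with `rows` (data.frame of
#'   repetition, fold, balanced_accuracy, per-class F1, macro_f1, chosen
#'   hyperparameters) and `model`, `feature_id`, `master_seed`.
#' @export
nested_cv_evaluate <- function(feature, labels, model = c("svm", "fnn"),
                               master_seed = 0L, config = NULL,
                               n_folds = 5L, n_repetitions = 5L) {
  model <- match.arg(model)
  ids <- rownames(feature)
  if (is.null(names(labels)) || !setequal(ids, names(labels)) ||
      length(labels) != length(ids)) {
    stop_tp("feature rows and labels are misaligned")
  }
  labels <- labels[ids]
  rows <- list()
  for (rep_i in seq_len(n_repetitions)) {
    rep_seed <- as.integer(master_seed) + rep_i
    fold <- stratified_folds(labels, n_folds = n_folds, seed = rep_seed)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      X_tr <- feature[tr, , drop = FALSE]
      X_te <- feature[!tr, , drop = FALSE]
      if (model == "svm") {
        cfg <- if (is.null(config)) svm_config() else config
        cfg$seed <- rep_seed * 100L + f
        fit <- fit_svm(X_tr, labels[tr], cfg)
      } else {
        cfg <- if (is.null(config)) fnn_config() else config
        cfg$seed <- rep_seed * 100L + f
        fit <- fit_fnn(X_tr, labels[tr], cfg)
      }
      pred <- predict(fit, X_te)
      sc <- metrics(labels[!tr], pred)
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = rep_i, fold = f,
        balanced_accuracy = sc$balanced_accuracy,
        f1_class1 = sc$f1_per_class[[1]],
        f1_class2 = sc$f1_per_class[[2]],
        macro_f1 = sc$macro_f1,
        chosen_k = if (model == "svm") fit$chosen$k else NA_integer_,
        chosen_C = if (model == "svm") fit$chosen$C else NA_real_)
    }
  }
  rows <- do.call(rbind, rows)
  cls <- sort(unique(as.character(labels)))
  names(rows)[names(rows) == "f1_class1"] <- paste0("f1_", cls[1])
  names(rows)[names(rows) == "f1_class2"] <- paste0("f1_", cls[2])
  structure(list(rows = rows, model = model,
                 feature_id = attr(feature, "feature_id"),
                 classes = cls, master_seed = master_seed),
            class = "evaluation_report")
}

#' Aggregate an evaluation report
#'
#' Arithmetic mean and sample (n - 1) standard deviation over the test-score
#' rows, per metric.
#'
#' @param report An `evaluation_report`.
#' @return data.frame with columns metric, mean, sd.
#' @export
aggregate_report <- function(report) {
  rows <- report$rows
  if (is.null(rows) || nrow(rows) == 0L) stop_tp("empty evaluation report")
  cols <- setdiff(names(rows),
                  c("repetition", "fold", "chosen_k", "chosen_C"))
  data.frame(metric = cols,
             mean = vapply(cols, function(cl) mean(rows[[cl]]), numeric(1)),
             sd = vapply(cols, function(cl) sd(rows[[cl]]), numeric(1)),
             row.names = NULL)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$model, " on ",
      x$feature_id %||% "<unnamed feature>", ": ",
      nrow(x$rows), " test scores\n", sep = "")
  print(aggregate_report(x))
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an evaluation report (per-row TSV + aggregate JSON)
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$rows, file.path(dir, "scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  agg <- aggregate_report(report)
  jsonlite::write_json(
    list(model = report$model, feature_id = report$feature_id,
         aggregates = agg),
    file.path(dir, "aggregates.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
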