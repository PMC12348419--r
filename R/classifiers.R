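#' SVM pipeline configuration
#'
#' @param C_grid Regularization candidates (default 0.1, 1, 10).
#' @param k_grid Candidate numbers of ANOVA-selected features; truncated at
#'   fit time to `min(k_cap, m')` where `m'` is the number of columns left
#'   after the variance filter.
#' @param k_cap Hard cap on selected features (default 200).
#' @param seed Integer seed for the inner cross-validation folds.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(C_grid = c(0.1, 1, 10),
                       k_grid = c(10L, 25L, 50L, 100L, 200L),
                       k_cap = 200L, seed = 0L) {
  if (any(k_grid > k_cap)) stop_tp("every k in k_grid must be <= k_cap")
  structure(list(C_grid = C_grid, k_grid = as.integer(k_grid),
                 k_cap = as.integer(k_cap), kernel = "rbf",
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' FNN configuration
#'
#' @param hidden_sizes Hidden-layer widths (default 512, 256, 128).
#' @param dropout_rate Dropout probability after each hidden layer.
#' @param batch_size Minibatch size (default 8).
#' @param epochs Training epochs (default 50).
#' @param learning_rate Adam step size (default 0.001).
#' @param decision_threshold Probability threshold; strictly greater is
#'   positive (default 0.5).
#' @param seed Integer seed for initialization and shuffling.
#' @return A list of class `fnn_config`.
#' @export
fnn_config <- function(hidden_sizes = c(512L, 256L, 128L),
                       dropout_rate = 0.5, batch_size = 8L, epochs = 50L,
                       learning_rate = 0.001, decision_threshold = 0.5,
                       seed = 0L) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_tp("dropout_rate must be in [0, 1)")
  }
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop_tp("decision_threshold must be in (0, 1)")
  }
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "fnn_config")
}

#' Remove features with exactly zero variance on the training data
#'
#' @param X Numeric matrix (training rows only).
#' @return List with `X` (filtered matrix) and `kept` (column names kept,
#'   to be re-applied to test data).
#' @export
variance_filter <- function(X) {
  X <- as.matrix(X)
  v <- apply(X, 2, var)
  kept <- colnames(X)[v > 0]
  if (!length(kept)) stop_tp("variance filter removed every feature")
  list(X = X[, kept, drop = FALSE], kept = kept)
}

#' One-way ANOVA F score per feature column
#'
#' F = (between-class sum of squares / (K - 1)) /
#'     (within-class sum of squares / (n - K)); features with the highest
#' score separate the class means most relative to within-class spread.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Class labels (length `nrow(X)`); each class needs >= 2 samples.
#' @return Named numeric vector of F scores (one per column; zero
#'   within-class variance with zero between-class variance gives NaN -> 0,
#'   positive between-class variance gives Inf).
#' @export
anova_f_scores <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  K <- length(classes)
  n <- nrow(X)
  sizes <- table(y)
  if (any(sizes < 2L)) {
    stop_tp("every class needs at least 2 samples for ANOVA F scores")
  }
  grand <- colMeans(X)
  ss_between <- 0; ss_within <- 0
  for (cl in classes) {
    rows <- X[y == cl, , drop = FALSE]
    mu <- colMeans(rows)
    ss_between <- ss_between + nrow(rows) * (mu - grand)^2
    ss_within <- ss_within + colSums(sweep(rows, 2, mu)^2)
  }
  f <- (ss_between / (K - 1)) / (ss_within / (n - K))
  f[ss_between == 0 & ss_within == 0] <- 0
  stats::setNames(f, colnames(X))
}

#' Select the k highest-scoring features
#'
#' Ties are broken by feature-name lexicographic order so selection is
#' deterministic across runs.
#'
#' @param scores Named F-score vector from [anova_f_scores()].
#' @param k Number of features to keep; must satisfy
#'   `k <= min(k_cap, length(scores))`.
#' @param k_cap Hard cap (default 200).
#' @return Character vector of the k selected feature names.
#' @export
select_top_k <- function(scores, k, k_cap = 200L) {
  m_prime <- length(scores)
  if (k < 1L || k > min(k_cap, m_prime)) {
    stop_tp("k = ", k, " out of bounds; must be in [1, min(", k_cap, ", ",
            m_prime, ")]")
  }
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(k)]
}

#' RBF kernel width from the training matrix
#'
#' gamma = 1 / (var(X) * m), where var(X) is the pooled variance of all
#' matrix entries and m the number of feature columns. Computed on the
#' matrix as passed to the kernel (i.e., after standardization in the
#' pipeline).
#'
#' @param X Numeric training matrix.
#' @return The kernel coefficient gamma.
#' @export
rbf_gamma <- function(X) {
  X <- as.matrix(X)
  v <- var(as.vector(X))
  if (!is.finite(v) || v == 0) stop_tp("zero pooled variance in training data")
  1 / (v * ncol(X))
}

#' Balanced class weights
#'
#' weight_i = n / (K * n_i): inverse-frequency weights that average to more
#' than 1 on minority classes so both classes carry equal total weight.
#'
#' @param y Class labels.
#' @return Named numeric vector, one weight per class.
#' @export
class_weights <- function(y) {
  y <- as.character(y)
  counts <- table(y)
  if (any(counts == 0L)) stop_tp("empty class")
  n <- length(y); K <- length(counts)
  w <- n / (K * as.numeric(counts))
  stats::setNames(w, names(counts))
}

# encode two-class labels to 0/1; positive class = second sorted level
#' @noRd
encode_labels <- function(y) {
  levels <- sort(unique(as.character(y)))
  if (length(levels) != 2L) {
    stop_tp("binary classification requires exactly 2 classes, got ",
            length(levels))
  }
  list(y01 = as.integer(as.character(y) == levels[2]), levels = levels)
}

# fit variance filter -> top-k ANOVA -> z-score on train, return state
#' @noRd
fit_preprocessing <- function(X, y, k, k_cap) {
  vf <- variance_filter(X)
  scores <- anova_f_scores(vf$X, y)
  selected <- select_top_k(scores, k, k_cap)
  Xs <- vf$X[, selected, drop = FALSE]
  center <- colMeans(Xs)
  scale_ <- apply(Xs, 2, sd)
  scale_[scale_ == 0] <- 1
  list(kept = vf$kept, selected = selected, center = center, scale = scale_)
}

#' @noRd
apply_preprocessing <- function(prep, X) {
  missing_cols <- setdiff(prep$selected, colnames(X))
  if (length(missing_cols)) {
    stop_tp("matrix is missing ", length(missing_cols),
            " feature column(s) recorded in the model, e.g. ",
            missing_cols[1])
  }
  Xs <- as.matrix(X)[, prep$selected, drop = FALSE]
  sweep(sweep(Xs, 2, prep$center), 2, prep$scale, "/")
}

#' Fit the SVM pipeline with inner grid search
#'
#' For every candidate (k, C): variance filter, top-k ANOVA selection,
#' column z-scoring, then a class-weighted RBF SVM with gamma from
#' [rbf_gamma()] and per-class bound `C * weight_i`. Candidates are scored
#' by mean balanced accuracy over a stratified 5-fold inner cross-validation
#' of the training split (ties: smallest k, then smallest C) and the winner
#' is refitted on the whole split. All preprocessing statistics come from
#' training rows only.
#'
#' @param X Training `feature_matrix` (samples x features).
#' @param y Binary labels aligned with `rownames(X)`.
#' @param config An [svm_config()].
#' @param inner_folds Number of inner CV folds (default 5).
#' @return A fitted model of class `transpred_model` (kind `"svm"`).
#' @export
fit_svm <- function(X, y, config = svm_config(), inner_folds = 5L) {
  X <- as.matrix(X)
  enc <- encode_labels(y)
  m_prime <- length(variance_filter(X)$kept)
  k_candidates <- sort(unique(pmin(config$k_grid,
                                   min(config$k_cap, m_prime))))
  grid <- expand.grid(k = k_candidates, C = sort(config$C_grid))
  grid <- grid[order(grid$k, grid$C), , drop = FALSE]  # tie-break order
  if (nrow(grid) > 1L) {
    min_class <- min(table(y))
    folds_n <- min(inner_folds, min_class)
    folds <- stratified_folds(stats::setNames(y, rownames(X)),
                              n_folds = folds_n, seed = config$seed)
    mean_ba <- vapply(seq_len(nrow(grid)), function(g) {
      bas <- vapply(seq_len(folds_n), function(f) {
        tr <- folds != f
        fit <- tryCatch(
          svm_pipeline_fit(X[tr, , drop = FALSE], y[tr],
                           grid$k[g], grid$C[g], config$k_cap),
          error = function(e) NULL)
        if (is.null(fit)) return(NA_real_)
        pred <- svm_pipeline_predict(fit, X[!tr, , drop = FALSE])
        metrics(y[!tr], pred)$balanced_accuracy
      }, numeric(1))
      mean(bas, na.rm = TRUE)
    }, numeric(1))
    # ties: smallest k, then smallest C (grid is ordered that way)
    best <- which(mean_ba >= max(mean_ba, na.rm = TRUE) - 1e-12)[1]
  } else {
    best <- 1L
  }
  fit <- svm_pipeline_fit(X, y, grid$k[best], grid$C[best], config$k_cap)
  structure(list(kind = "svm", prep = fit$prep, core = fit$core,
                 chosen = list(k = grid$k[best], C = grid$C[best]),
                 levels = enc$levels, config = config),
            class = "transpred_model")
}

#' @noRd
svm_pipeline_fit <- function(X, y, k, C, k_cap) {
  enc <- encode_labels(y)
  prep <- fit_preprocessing(X, y, k, k_cap)
  Xz <- apply_preprocessing(prep, X)
  gamma <- rbf_gamma(Xz)
  w <- class_weights(enc$y01)
  core <- svm_core_fit(Xz, enc$y01, C, gamma, w)
  list(prep = prep, core = core, levels = enc$levels)
}

#' @noRd
svm_pipeline_predict <- function(fit, X) {
  Xz <- apply_preprocessing(fit$prep, X)
  dec <- svm_core_decision(fit$core, Xz)
  fit$levels[ifelse(dec > 0, 2L, 1L)]
}

#' Predict labels with a fitted model
#'
#' SVM: sign of the decision function. FNN: positive iff the predicted
#' probability is strictly greater than the decision threshold (p = 0.5 is
#' negative).
#'
#' @param object A `transpred_model`.
#' @param X Feature matrix carrying at least the feature columns recorded in
#'   the model's preprocessing state.
#' @param ... Unused.
#' @return Character vector of predicted labels; for FNN models the
#'   probabilities are attached as attribute `"prob"`.
#' @export
predict.transpred_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (object$kind == "svm") {
    svm_pipeline_predict(object, X)
  } else {
    p <- fnn_forward_prob(object$net, apply_preprocessing(object$prep, X))
    lab <- object$levels[ifelse(p > object$config$decision_threshold, 2L, 1L)]
    structure(lab, prob = p)
  }
}

#' Save a fitted model to a directory
#'
#' Layout: `model.rds` (preprocessing state + parameters) plus
#' `model_info.json` (kind, chosen hyperparameters, label levels) for
#' human inspection.
#'
#' @param model A `transpred_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  info <- list(kind = model$kind, levels = model$levels,
               chosen = model$chosen,
               n_selected = length(model$prep$selected))
  jsonlite::write_json(info, file.path(dir, "model_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a model saved by [save_model()]
#'
#' @param dir Model directory.
#' @return The `transpred_model`.
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
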