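# average path length of an unsuccessful BST search over n points; the
# isolation-forest normalizing constant c(n)
#' @noRd
avg_path_length <- function(n) {
  if (n <= 1) return(0)
  if (n == 2) return(1)
  2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
}

# one isolation tree over the rows of x (a subsample); recursive list
#' @noRd
build_itree <- function(x, depth, max_depth) {
  n <- nrow(x)
  if (n <= 1L || depth >= max_depth) {
    return(list(leaf = TRUE, size = n))
  }
  rng <- apply(x, 2, range)
  splittable <- which(rng[2, ] > rng[1, ])
  if (!length(splittable)) return(list(leaf = TRUE, size = n))
  j <- if (length(splittable) == 1L) splittable else sample(splittable, 1L)
  split <- runif(1, rng[1, j], rng[2, j])
  left <- x[, j] < split
  list(leaf = FALSE, feature = j, split = split,
       left = build_itree(x[left, , drop = FALSE], depth + 1L, max_depth),
       right = build_itree(x[!left, , drop = FALSE], depth + 1L, max_depth))
}

# path lengths of all rows of x under one tree
#' @noRd
itree_path_lengths <- function(tree, x) {
  out <- numeric(nrow(x))
  recurse <- function(node, idx, depth) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx] <<- depth + avg_path_length(node$size)
      return()
    }
    left <- x[idx, node$feature] < node$split
    recurse(node$left, idx[left], depth + 1L)
    recurse(node$right, idx[!left], depth + 1L)
  }
  recurse(tree, seq_len(nrow(x)), 0)
  out
}

#' Isolation-forest anomaly scores
#'
#' Ensemble of random isolation trees, each grown on a subsample of
#' `min(256, n)` rows to depth at most `ceiling(log2(subsample))`. The score
#' of a sample is `2^(-E[h(x)] / c(psi))` where `h` is the path length and
#' `c` the normalizing average path length; scores near 1 indicate
#' anomalies, scores well below 0.5 indicate normal points.
#'
#' @param x Numeric matrix, samples in rows.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed; the forest is deterministic given it.
#' @return Numeric vector of anomaly scores in (0, 1).
#' @export
isolation_forest_scores <- function(x, n_trees = 100L, seed = 0L) {
  x <- as.matrix(x)
  n <- nrow(x)
  psi <- min(256L, n)
  max_depth <- ceiling(log2(psi))
  withr::with_seed(seed, {
    paths <- matrix(0, n, n_trees)
    for (t in seq_len(n_trees)) {
      idx <- sample.int(n, psi)
      tree <- build_itree(x[idx, , drop = FALSE], 0L, max_depth)
      paths[, t] <- itree_path_lengths(tree, x)
    }
  })
  2^(-rowMeans(paths) / avg_path_length(psi))
}

#' Detect outliers in one feature dataset
#'
#' Pipeline: (i) z-score every feature column (zero-variance columns are
#' dropped); (ii) project onto the smallest number of principal components
#' whose cumulative explained variance reaches `var_explained`; (iii) score
#' samples with an isolation forest and flag those above the conventional
#' automatic threshold of the normalized path-length score (0.5).
#'
#' @param fm A `feature_matrix` (or plain matrix with rownames).
#' @param seed Integer seed for the forest.
#' @param var_explained Cumulative explained-variance target (default 0.95).
#' @param n_trees Number of isolation trees (default 100).
#' @return Character vector of flagged accessions, with attributes
#'   `n_components`, `explained_variance` (cumulative, retained components)
#'   and `scores` (all samples).
#' @export
detect_outliers_single <- function(fm, seed = 0L, var_explained = 0.95,
                                   n_trees = 100L) {
  x <- as.matrix(fm)
  if (nrow(x) < 2L) stop_tp("outlier detection needs at least 2 samples")
  if (nrow(x) < 10L) {
    warning("outlier detection on fewer than 10 samples is unreliable",
            call. = FALSE)
  }
  sds <- apply(x, 2, sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 0L) stop_tp("all feature columns are constant")
  x <- scale(x)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cumvar >= var_explained)[1]
  proj <- pc$x[, seq_len(k), drop = FALSE]
  scores <- isolation_forest_scores(proj, n_trees = n_trees, seed = seed)
  flagged <- rownames(x)[scores > 0.5]
  structure(flagged, n_components = k, explained_variance = cumvar[k],
            scores = stats::setNames(scores, rownames(x)))
}

#' Consensus outliers across feature datasets
#'
#' A sample is a consensus outlier iff it is flagged in at least `fraction`
#' of the feature datasets (inclusive).
#'
#' @param per_feature_flags Named list mapping feature id to the character
#'   vector of accessions flagged in that feature dataset.
#' @param n_feature_datasets Number of feature datasets that participated;
#'   defaults to `length(per_feature_flags)`.
#' @param fraction Consensus fraction (default 0.5).
#' @return Character vector of consensus-outlier accessions.
#' @export
consensus_outliers <- function(per_feature_flags,
                               n_feature_datasets = length(per_feature_flags),
                               fraction = 0.5) {
  if (n_feature_datasets < 1L) stop_tp("need at least one feature dataset")
  accs <- unique(unlist(per_feature_flags))
  if (!length(accs)) return(character(0))
  counts <- vapply(accs, function(a) {
    sum(vapply(per_feature_flags, function(f) a %in% f, logical(1)))
  }, numeric(1))
  sort(accs[counts >= fraction * n_feature_datasets])
}

#' Run the consensus outlier pipeline over several feature datasets
#'
#' @param feature_matrices Named list of `feature_matrix` objects over the
#'   same samples.
#' @param seed Integer seed shared across the per-feature detectors.
#' @param fraction Consensus fraction (default 0.5).
#' @return A list of class `outlier_report` with `per_feature_flags`,
#'   `consensus` and `fraction_threshold`.
#' @export
outlier_report <- function(feature_matrices, seed = 0L, fraction = 0.5) {
  flags <- lapply(feature_matrices, detect_outliers_single, seed = seed)
  flags <- lapply(flags, as.character)
  structure(list(per_feature_flags = flags,
                 consensus = consensus_outliers(flags, fraction = fraction),
                 fraction_threshold = fraction),
            class = "outlier_report")
}

#' Export an outlier report as TSV
#'
#' One row per sample that was flagged anywhere: accession, one logical
#' column per feature dataset, and the consensus flag.
#'
#' @param report An `outlier_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_outlier_report <- function(report, path) {
  accs <- sort(unique(unlist(report$per_feature_flags)))
  df <- data.frame(accession = accs)
  for (id in names(report$per_feature_flags)) {
    df[[id]] <- accs %in% report$per_feature_flags[[id]]
  }
  df$consensus <- accs %in% report$consensus
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
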