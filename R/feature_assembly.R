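#' Mean-pool a per-residue embedding matrix
#'
#' Averages the n x d matrix of per-residue embeddings over all residue
#' positions, yielding one d-dimensional vector per protein.
#'
#' @param emb Numeric matrix, rows = residues, columns = embedding
#'   dimensions.
#' @return Numeric vector of length `ncol(emb)`.
#' @export
mean_pool <- function(emb) {
  emb <- as.matrix(emb)
  if (nrow(emb) == 0L) stop_tp("cannot pool an empty embedding matrix")
  colMeans(emb)
}

#' Deterministic uniform-random dummy feature
#'
#' A non-informative feature of `dim` values drawn from U(0, 1), seeded from
#' a stable hash of the accession mixed with a global seed, so the vector of
#' a protein never depends on dataset order. Used to calibrate chance-level
#' performance of the evaluation protocol.
#'
#' @param accession Protein accession.
#' @param global_seed Integer master seed.
#' @param dim Vector length (default 1024).
#' @return Numeric vector in \[0, 1).
#' @export
dummy_feature <- function(accession, global_seed, dim = 1024L) {
  mix <- (string_hash(accession) + (global_seed %% 2147483647) * 1000003) %%
    2147483647
  withr::with_seed(as.integer(mix), runif(dim))
}

#' META feature: AAC | PAAC | Multi-PSSM concatenation
#'
#' @param aac 20-dim amino-acid composition (prefixed names).
#' @param paac 400-dim pair composition.
#' @param multipssm 1600-dim Multi-PSSM vector.
#' @return Named numeric vector of length 2020.
#' @export
meta_feature <- function(aac, paac, multipssm) {
  check_block <- function(v, n, what) {
    if (length(v) != n) {
      stop_tp(what, " block must have ", n, " dimensions, got ", length(v))
    }
  }
  check_block(aac, 20L, "AAC")
  check_block(paac, 400L, "PAAC")
  check_block(multipssm, 1600L, "Multi-PSSM")
  combine_features(list(aac, paac, multipssm))
}

#' META-STD fingerprint: per-sample per-block z-scoring then concatenation
#'
#' Each constituent block is standardized within the sample (its own mean
#' subtracted, divided by its own standard deviation) before concatenation,
#' so no information is shared between samples. A constant block maps to
#' zeros.
#'
#' @inheritParams meta_feature
#' @return Named numeric vector of length 2020.
#' @export
meta_std_feature <- function(aac, paac, multipssm) {
  zscore_block <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) return(v * 0)
    (v - mean(v)) / s
  }
  meta_feature(zscore_block(aac), zscore_block(paac), zscore_block(multipssm))
}

#' Assemble a feature matrix from per-protein vectors
#'
#' @param vectors Named list mapping accession to a numeric feature vector;
#'   `NULL` entries (e.g., proteins missing a constituent input) are dropped
#'   with a warning.
#' @param feature_id Tag recorded on the matrix (e.g., `"3Di-KMER2"`).
#' @return A `feature_matrix`: numeric matrix with accession rownames sorted
#'   lexicographically, feature-name colnames, and a `feature_id` attribute.
#' @export
build_feature_matrix <- function(vectors, feature_id) {
  missing_idx <- vapply(vectors, is.null, logical(1))
  if (any(missing_idx)) {
    warning("dropping ", sum(missing_idx), " sample(s) with missing ",
            feature_id, " input: ",
            paste(names(vectors)[missing_idx], collapse = ", "),
            call. = FALSE)
    vectors <- vectors[!missing_idx]
  }
  if (length(vectors) == 0L) stop_tp("no samples left to assemble")
  lens <- lengths(vectors)
  if (length(unique(lens)) != 1L) {
    stop_tp("inconsistent feature vector lengths: ",
            paste(unique(lens), collapse = ", "))
  }
  if (is.null(names(vectors)) || anyDuplicated(names(vectors))) {
    stop_tp("vectors must be uniquely named by accession")
  }
  ord <- order(names(vectors))
  values <- do.call(rbind, vectors[ord])
  fnames <- names(vectors[[1]])
  if (is.null(fnames)) fnames <- paste0(feature_id, ".", seq_len(ncol(values)))
  if (!all(startsWith(fnames, feature_id))) {
    fnames <- paste0(feature_id, ".", fnames)
  }
  colnames(values) <- fnames
  feature_matrix(values, feature_id)
}

#' Construct a feature_matrix from a plain matrix
#'
#' @param values Numeric matrix with sample rownames and feature colnames.
#' @param feature_id Feature tag string.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, feature_id) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop_tp("feature matrix needs sample ids")
  if (anyDuplicated(rownames(values))) stop_tp("duplicate sample ids")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(feature_id, ".", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) stop_tp("duplicate feature names")
  if (anyNA(values)) stop_tp("feature matrix contains missing values")
  structure(values, feature_id = feature_id,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", attr(x, "feature_id"), ": ",
      nrow(x), " samples x ", ncol(x), " features\n", sep = "")
  invisible(x)
}

# subsetting keeps class/attr
#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    structure(out, feature_id = attr(x, "feature_id"),
              class = c("feature_matrix", "matrix", "array"))
  } else out
}

#' Export a feature matrix as TSV (samples x features, header row)
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_feature_matrix <- function(fm, path) {
  df <- data.frame(accession = rownames(fm), fm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a feature matrix written by [export_feature_matrix()]
#'
#' @param path TSV path.
#' @param feature_id Feature tag to record; defaults to the common prefix of
#'   the column names, else the file name stem.
#' @return A `feature_matrix`.
#' @export
import_feature_matrix <- function(path, feature_id = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  if (is.null(feature_id)) {
    feature_id <- sub("\\..*$", "", colnames(values)[1])
    if (!nzchar(feature_id)) feature_id <- sub("\\.tsv$", "", basename(path))
  }
  feature_matrix(values, feature_id)
}

#' Write per-residue embeddings as a directory of TSV files
#'
#' One plain-text matrix per accession (`<accession>.tsv`), a keyed-array
#' container that round-trips exactly at full double precision.
#'
#' @param embeddings Named list of n x d numeric matrices.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_embeddings <- function(embeddings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (acc in names(embeddings)) {
    write.table(format(embeddings[[acc]], digits = 17),
                file.path(dir, paste0(acc, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(dir)
}

#' Read an embedding container written by [write_embeddings()]
#'
#' @param dir Container directory.
#' @return Named list of numeric matrices.
#' @export
read_embeddings <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, function(f) {
    as.matrix(read.delim(f, header = FALSE))
  })
  names(out) <- sub("\\.tsv$", "", basename(files))
  lapply(out, unname)
}
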