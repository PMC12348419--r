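# Synthetic generators: class-conditional Dirichlet composition biases for
# AA and 3Di sequences, log-odds PSSMs, embedding matrices with class
# signal, and planted outliers. These emulate the compositional shifts the
# implemented features detect; they are a stand-in for real data, not a
# biological simulation.

#' Synthetic dataset specification
#'
#' @param n_per_class Integer vector of length 2: class sizes (default
#'   26/28, the size and split of the two-class carrier benchmark).
#' @param length_range Sequence length range in residues (default 200-800,
#'   typical membrane-transporter lengths).
#' @param signal Dirichlet-bias separation delta >= 0 between the two class
#'   compositional distributions; 0 means class-identical generators.
#' @param concentration Dirichlet concentration controlling within-class
#'   compositional variability (default 50).
#' @param embedding_dim Embedding dimensionality (default 1024).
#' @param embedding_signal Distance between class-mean embedding vectors.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(26L, 28L),
                           length_range = c(200L, 800L),
                           signal = 0.3, concentration = 50,
                           embedding_dim = 1024L, embedding_signal = 1,
                           seed = 0L) {
  if (signal < 0 || signal >= 1) stop_tp("signal must be in [0, 1)")
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 signal = signal, concentration = concentration,
                 embedding_dim = as.integer(embedding_dim),
                 embedding_signal = embedding_signal,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# class-specific Dirichlet mean: uniform tilted by +/- delta on alternating
# letter blocks, sign flipped between classes; phase shifts the pattern so
# the AA and 3Di channels carry independent signal
#' @noRd
class_composition_mean <- function(class_idx, delta, phase = 0L) {
  s <- rep(c(1, -1), each = 10L)
  s <- s[((seq_len(20L) - 1L + phase) %% 20L) + 1L]
  if (class_idx == 2L) s <- -s
  m <- (1 + delta * s) / 20
  m / sum(m)
}

#' @noRd
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate labeled AA + 3Di sequence pairs
#'
#' Per protein, a composition is drawn from a Dirichlet centered on the
#' class-specific tilted-uniform mean, then residues are sampled i.i.d.
#' The paired 3Di sequence has identical length and its own class bias.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `proteins` (named list of `protein_record`),
#'   `tdi` (named list of `tdi_record`) and `labels` (named character
#'   vector, classes `"classA"`/`"classB"`).
#' @export
gen_labeled_sequences <- function(spec) {
  withr::with_seed(spec$seed, {
    proteins <- list(); tdi <- list(); labels <- character(0)
    counter <- 0L
    for (cl in 1:2) {
      mu_aa <- class_composition_mean(cl, spec$signal, phase = 0L)
      mu_td <- class_composition_mean(cl, spec$signal, phase = 5L)
      for (i in seq_len(spec$n_per_class[cl])) {
        counter <- counter + 1L
        acc <- sprintf("SYN%04d", counter)
        L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
        p_aa <- rdirichlet1(spec$concentration * 20 * mu_aa)
        p_td <- rdirichlet1(spec$concentration * 20 * mu_td)
        aa <- paste(sample(AA_ALPHABET, L, replace = TRUE, prob = p_aa),
                    collapse = "")
        td <- paste(sample(TDI_ALPHABET, L, replace = TRUE, prob = p_td),
                    collapse = "")
        proteins[[acc]] <- protein_record(acc, aa)
        tdi[[acc]] <- tdi_record(acc, td)
        labels[acc] <- c("classA", "classB")[cl]
      }
    }
    list(proteins = proteins, tdi = tdi, labels = labels)
  })
}

#' Generate synthetic PSSMs (all four search configurations per protein)
#'
#' Integer log-odds rows are drawn around a residue-dependent mean (a
#' diagonal conservation bonus) plus a class-dependent shift scaled by
#' `signal`, with rounding noise, for each of the four
#' (database, iterations) configurations.
#'
#' @param proteins Named list of `protein_record`s.
#' @param labels Named class labels.
#' @param signal Class shift magnitude on the log-odds scale.
#' @param seed Integer seed.
#' @return Named list (per accession) of named lists (per configuration
#'   `"<db>_<iters>"`) of `pssm` objects.
#' @export
gen_pssms <- function(proteins, labels, signal = 1, seed = 0L) {
  withr::with_seed(seed, {
    out <- list()
    for (acc in names(proteins)) {
      cl <- match(labels[[acc]], sort(unique(unlist(labels))))
      shift <- signal * (if (cl == 1L) 1 else -1) *
        rep(c(1, -1), length.out = 20L)
      seq_ <- proteins[[acc]]$seq
      n <- nchar(seq_)
      res_idx <- match(strsplit(seq_, "")[[1]], AA_ALPHABET)
      cfgs <- list()
      for (db in c("uniref50", "uniref90")) {
        for (it in c(1L, 3L)) {
          base <- matrix(rnorm(n * 20L, sd = 2), n, 20L)
          base <- sweep(base, 2, shift, "+")
          base[cbind(seq_len(n), res_idx)] <-
            base[cbind(seq_len(n), res_idx)] + 4
          cfgs[[paste0(db, "_", it)]] <-
            pssm(acc, seq_, round(base), database_tag = db, iterations = it)
        }
      }
      out[[acc]] <- cfgs
    }
    out
  })
}

#' Generate synthetic per-residue embeddings
#'
#' Rows are the class mean vector (a unit direction scaled by `signal`,
#' sign-flipped between classes) plus isotropic unit noise.
#'
#' @param proteins Named list of `protein_record`s.
#' @param labels Named class labels.
#' @param dim Embedding dimensionality (default 1024).
#' @param signal Distance scale between class means.
#' @param seed Integer seed.
#' @return Named list of n x dim matrices.
#' @export
gen_embeddings <- function(proteins, labels, dim = 1024L, signal = 1,
                           seed = 0L) {
  withr::with_seed(seed, {
    direction <- rnorm(dim)
    direction <- direction / sqrt(sum(direction^2))
    out <- list()
    for (acc in names(proteins)) {
      cl <- match(labels[[acc]], sort(unique(unlist(labels))))
      mu <- signal * (if (cl == 1L) 1 else -1) * direction
      n <- nchar(proteins[[acc]]$seq)
      out[[acc]] <- matrix(rnorm(n * dim), n, dim) +
        matrix(mu, n, dim, byrow = TRUE)
    }
    out
  })
}

#' Plant outliers into a feature matrix
#'
#' Displaces randomly chosen rows by `magnitude_sigma` per-column standard
#' deviations along a random unit direction; the planted accessions are
#' returned as ground truth.
#'
#' @param fm A `feature_matrix`.
#' @param n_outliers Number of rows to displace (< number of samples).
#' @param magnitude_sigma Displacement in per-column SD units (> 0).
#' @param seed Integer seed.
#' @return List with `matrix` (modified `feature_matrix`) and `planted`
#'   (character vector of displaced accessions).
#' @export
plant_outliers <- function(fm, n_outliers = 1L, magnitude_sigma = 10,
                           seed = 0L) {
  if (magnitude_sigma <= 0) stop_tp("magnitude_sigma must be > 0")
  x <- as.matrix(fm)
  if (n_outliers >= nrow(x)) stop_tp("n_outliers must be < number of samples")
  withr::with_seed(seed, {
    rows <- sample.int(nrow(x), n_outliers)
    sds <- apply(x, 2, sd)
    sds[sds == 0] <- 1
    for (r in rows) {
      u <- rnorm(ncol(x))
      u <- u / sqrt(sum(u^2)) * sqrt(ncol(x))  # unit scale per column
      x[r, ] <- x[r, ] + magnitude_sigma * sds * u
    }
  })
  list(matrix = feature_matrix(x, attr(fm, "feature_id")),
       planted = rownames(x)[rows])
}

#' Write a synthetic data bundle to disk
#'
#' Emits the file formats the pipeline consumes: AA and 3Di FASTA, ASCII
#' PSSMs in the cache layout `<db>_<iters>/<accession>.pssm`, an embedding
#' container, and a labels TSV.
#'
#' @param spec A [synthetic_spec()].
#' @param out Output directory.
#' @param with_pssms,with_embeddings Emit those (slower) components.
#' @return `out`, invisibly.
#' @export
export_synthetic_bundle <- function(spec, out, with_pssms = TRUE,
                                    with_embeddings = FALSE) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  data <- gen_labeled_sequences(spec)
  write_fasta(data$proteins, file.path(out, "sequences_aa.fasta"))
  write_fasta(data$tdi, file.path(out, "sequences_3di.fasta"))
  write.table(data.frame(accession = names(data$labels),
                         label = unname(data$labels)),
              file.path(out, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (with_pssms) {
    pssms <- gen_pssms(data$proteins, data$labels, seed = spec$seed)
    for (acc in names(pssms)) {
      for (cfg in names(pssms[[acc]])) {
        dir.create(file.path(out, cfg), showWarnings = FALSE)
        write_ascii_pssm(pssms[[acc]][[cfg]],
                         file.path(out, cfg, paste0(acc, ".pssm")))
      }
    }
  }
  if (with_embeddings) {
    emb <- gen_embeddings(data$proteins, data$labels,
                          dim = spec$embedding_dim,
                          signal = spec$embedding_signal, seed = spec$seed)
    write_embeddings(emb, file.path(out, "embeddings"))
  }
  invisible(out)
}

#' Dummy-feature matrix for a set of accessions
#'
#' Convenience wrapper building the deterministic uniform-random feature
#' matrix used for chance-level calibration.
#'
#' @param accessions Character vector of sample ids.
#' @param global_seed Integer master seed.
#' @param dim Vector length per sample (default 1024).
#' @return A `feature_matrix` tagged `"DUMMY"`.
#' @export
dummy_feature_matrix <- function(accessions, global_seed = 0L, dim = 1024L) {
  vecs <- lapply(accessions, dummy_feature, global_seed = global_seed,
                 dim = dim)
  names(vecs) <- accessions
  build_feature_matrix(vecs, "DUMMY")
}

#' k-mer feature matrix from record lists
#'
#' @param feature_id One of the k-mer feature ids of [named_feature()].
#' @param proteins Named list of `protein_record`s (or `NULL`).
#' @param tdi Named list of `tdi_record`s (or `NULL`).
#' @return A `feature_matrix`.
#' @export
kmer_feature_matrix <- function(feature_id, proteins = NULL, tdi = NULL) {
  accs <- names(if (!is.null(proteins)) proteins else tdi)
  vecs <- lapply(accs, function(acc) {
    named_feature(feature_id,
                  seq_aa = if (!is.null(proteins)) proteins[[acc]]$seq,
                  seq_3di = if (!is.null(tdi)) tdi[[acc]]$seq)
  })
  names(vecs) <- accs
  build_feature_matrix(vecs, feature_id)
}
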