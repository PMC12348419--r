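# shared fixture builders; everything is generated in code at test time

aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(n, seed = NULL, alphabet = aa_letters) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_pssm <- function(n, seed = 1, accession = "P1",
                        database_tag = "uniref50", iterations = 1L) {
  set.seed(seed)
  transpred::pssm(accession, random_seq(n),
                  matrix(sample(-8:8, n * 20, replace = TRUE), n, 20),
                  database_tag = database_tag, iterations = iterations)
}

# small labeled gaussian blob feature matrix, two classes
blob_matrix <- function(n_per_class = 30, d = 10, sep = 4, seed = 1,
                        feature_id = "BLOB") {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * d), n, d)
  x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] + sep
  rownames(x) <- sprintf("S%03d", seq_len(n))
  labels <- stats::setNames(rep(c("neg", "pos"), each = n_per_class),
                            rownames(x))
  list(fm = transpred::feature_matrix(x, feature_id), labels = labels)
}

mini_obo_path <- function() {
  system.file("extdata", "mini_go.obo", package = "transpred")
}
mini_gaf_path <- function() {
  system.file("extdata", "mini_go.gaf", package = "transpred")
}
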