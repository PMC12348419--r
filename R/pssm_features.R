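#' Construct a PSSM object
#'
#' @param accession Protein accession.
#' @param sequence Amino-acid sequence of length n.
#' @param log_odds n x 20 integer matrix of log-odds scores, columns in the
#'   fixed alphabet order `ACDEFGHIKLMNPQRSTVWY`.
#' @param database_tag `"uniref50"` or `"uniref90"`.
#' @param iterations 1 or 3 search iterations.
#' @return A list of class `pssm`.
#' @export
pssm <- function(accession, sequence, log_odds,
                 database_tag = c("uniref50", "uniref90"),
                 iterations = 1L) {
  database_tag <- match.arg(database_tag)
  if (!iterations %in% c(1L, 3L)) stop_tp("iterations must be 1 or 3")
  log_odds <- as.matrix(log_odds)
  if (nrow(log_odds) != nchar(sequence)) {
    stop_tp("PSSM row count (", nrow(log_odds), ") does not match sequence ",
            "length (", nchar(sequence), ")")
  }
  if (ncol(log_odds) != 20L) stop_tp("PSSM must have 20 columns")
  if (any(log_odds != round(log_odds))) {
    stop_tp("log-odds scores must be integers")
  }
  colnames(log_odds) <- AA_ALPHABET
  structure(list(accession = accession, sequence = toupper(sequence),
                 log_odds = log_odds, database_tag = database_tag,
                 iterations = as.integer(iterations)),
            class = "pssm")
}

#' Parse an ASCII PSSM file
#'
#' Reads the standard ASCII PSSM produced by iterative profile search: two
#' header lines, a column-header line, then one row per position carrying the
#' position index, the residue letter, 20 integer log-odds columns (kept) and
#' 20 frequency columns plus trailing statistics (ignored).
#'
#' @param path Path to the ASCII PSSM file.
#' @param accession Accession to record; defaults to the file name stem.
#' @param database_tag,iterations Search metadata to attach.
#' @return A `pssm` object.
#' @export
parse_ascii_pssm <- function(path, accession = NULL,
                             database_tag = "uniref50", iterations = 1L) {
  if (is.null(accession)) {
    accession <- sub("\\.pssm$", "", basename(path))
  }
  lines <- readLines(path)
  # data rows start with an integer position index
  is_row <- grepl("^\\s*[0-9]+\\s+[A-Z]\\s", lines)
  if (!any(is_row)) stop_tp("no PSSM rows found in ", path)
  rows <- which(is_row)
  n <- length(rows)
  log_odds <- matrix(0L, n, 20L)
  residues <- character(n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[rows[i]]), "\\s+")[[1]]
    if (length(fields) < 22L) {
      stop_tp("malformed PSSM row at line ", rows[i], " of ", path,
              ": expected at least 22 fields, got ", length(fields))
    }
    scores <- suppressWarnings(as.integer(fields[3:22]))
    if (anyNA(scores)) {
      stop_tp("non-integer score in PSSM row at line ", rows[i], " of ", path)
    }
    residues[i] <- fields[2]
    log_odds[i, ] <- scores
  }
  pssm(accession, paste(residues, collapse = ""), log_odds,
       database_tag = database_tag, iterations = iterations)
}

#' Write a PSSM in the ASCII format read by [parse_ascii_pssm()]
#'
#' Fixture/export writer mirroring the iterative-search ASCII layout closely
#' enough for round-trip parsing (log-odds block, dummy frequency block,
#' trailing statistics).
#'
#' @param x A `pssm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", AA_ALPHABET), collapse = ""),
           "   ", paste(sprintf("%3s", AA_ALPHABET), collapse = ""))), con)
  chars <- strsplit(x$sequence, "")[[1]]
  for (i in seq_len(nrow(x$log_odds))) {
    writeLines(paste0(sprintf("%5d %s ", i, chars[i]),
                      paste(sprintf("%3d", x$log_odds[i, ]), collapse = ""),
                      "  ",
                      paste(sprintf("%4d", rep(0L, 20L)), collapse = ""),
                      sprintf("  %4.2f %8.2f", 0, 0)), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3113"), con)
  invisible(path)
}

#' Evolutionary conservation profile of a protein
#'
#' For every amino-acid type, the log-odds rows of the PSSM at all positions
#' carrying that type are averaged, giving a 20 x 20 matrix (row = residue
#' type, column = substitution target). Rows for residue types absent from
#' the sequence are zero.
#'
#' @param x A `pssm` object.
#' @return 20 x 20 numeric matrix with dimnames over the alphabet.
#' @export
conservation_profile <- function(x) {
  stopifnot(inherits(x, "pssm"))
  chars <- strsplit(x$sequence, "")[[1]]
  prof <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (a in AA_ALPHABET) {
    idx <- which(chars == a)
    if (length(idx)) {
      prof[a, ] <- colMeans(x$log_odds[idx, , drop = FALSE])
    }
  }
  prof
}

# fixed Multi-PSSM block order
MULTI_PSSM_CONFIGS <- c("uniref50_1", "uniref50_3", "uniref90_1", "uniref90_3")

#' Multi-PSSM feature vector
#'
#' Flattens four conservation profiles — one per (database, iterations)
#' configuration — row-major and concatenates them in the fixed order
#' uniref50/1, uniref50/3, uniref90/1, uniref90/3, giving 1600 dimensions.
#'
#' @param profiles Named list of 20 x 20 profiles; names are
#'   `"<database_tag>_<iterations>"`.
#' @return Named numeric vector of length 1600.
#' @export
multi_pssm <- function(profiles) {
  missing_cfg <- setdiff(MULTI_PSSM_CONFIGS, names(profiles))
  if (length(missing_cfg)) {
    stop_tp("missing PSSM configuration(s): ",
            paste(missing_cfg, collapse = ", "))
  }
  blocks <- lapply(MULTI_PSSM_CONFIGS, function(cfg) {
    prof <- profiles[[cfg]]
    stopifnot(identical(dim(prof), c(20L, 20L)))
    v <- as.vector(t(prof))  # row-major
    names(v) <- paste0("MULTI-PSSM.", cfg, ".",
                       rep(AA_ALPHABET, each = 20L), ".",
                       rep(AA_ALPHABET, times = 20L))
    v
  })
  combine_features(blocks)
}

#' Compute the Multi-PSSM feature from a list of PSSMs of one protein
#'
#' @param pssms List of four `pssm` objects covering the configurations
#'   uniref50/uniref90 x 1/3 iterations.
#' @return Named numeric vector of length 1600.
#' @export
multi_pssm_from_pssms <- function(pssms) {
  profiles <- lapply(pssms, conservation_profile)
  names(profiles) <- vapply(pssms, function(p) {
    paste0(p$database_tag, "_", p$iterations)
  }, character(1))
  multi_pssm(profiles)
}
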