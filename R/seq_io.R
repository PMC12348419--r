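#' Read an AA or 3Di FASTA file
#'
#' Parses a FASTA file into a list of records. The accession is the first
#' whitespace-delimited header token, except for structure-database style
#' headers of the form `AF-<accession>-F<n>...`, where the token between the
#' first and second dash is taken. Sequences are uppercased and validated
#' against the declared 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"AA"` for amino-acid sequences or `"3Di"` for structural
#'   state sequences. Both alphabets contain the same 20 uppercase letters.
#' @return A named list of records; each record is a list with `accession`
#'   and `seq`. For `alphabet = "AA"` records also carry default curation
#'   flags (`reviewed`, `fragment`, `existence_evidence`, `gene_names`).
#' @export
read_fasta <- function(path, alphabet = c("AA", "3Di")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_tp("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  accs <- vapply(names(set), extract_accession, character(1), USE.NAMES = FALSE)
  seqs <- toupper(as.character(set))
  allowed <- if (alphabet == "AA") AA_ALPHABET else TDI_ALPHABET
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    validate_sequence(seqs[[i]], allowed, accs[[i]])
    records[[i]] <- if (alphabet == "AA") {
      protein_record(accs[[i]], seqs[[i]])
    } else {
      tdi_record(accs[[i]], seqs[[i]])
    }
  }
  if (anyDuplicated(accs)) {
    stop_tp("duplicate accession in ", path, ": ",
            accs[duplicated(accs)][1])
  }
  names(records) <- accs
  records
}

#' Write records to a FASTA file
#'
#' @param records List of records as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.list(records)) {
    seqs <- vapply(records, function(r) r$seq, character(1))
    names(seqs) <- vapply(records, function(r) r$accession, character(1))
  } else {
    seqs <- records
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @noRd
extract_accession <- function(header) {
  tok <- strsplit(trimws(header), "[[:space:]]+")[[1]][1]
  if (grepl("^AF-[^-]+-F[0-9]+", tok)) {
    strsplit(tok, "-", fixed = TRUE)[[1]][2]
  } else {
    tok
  }
}

#' @noRd
validate_sequence <- function(seq, allowed, accession) {
  if (nchar(seq) == 0L) stop_tp("empty sequence for record ", accession)
  chars <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    stop_tp("record ", accession, " contains characters outside the ",
            "declared alphabet: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a protein record
#'
#' @param accession Accession string.
#' @param aa_seq Amino-acid sequence (uppercased).
#' @param reviewed Manually-curated (Swiss-Prot-like) flag.
#' @param fragment Sequence-fragment flag.
#' @param existence_evidence Ordinal protein-existence level (1 = evidence at
#'   protein level).
#' @param gene_names Character vector of gene names.
#' @return A list of class `protein_record`.
#' @export
protein_record <- function(accession, aa_seq, reviewed = TRUE,
                           fragment = FALSE, existence_evidence = 1L,
                           gene_names = character(0)) {
  structure(list(accession = accession, seq = toupper(aa_seq),
                 reviewed = reviewed, fragment = fragment,
                 existence_evidence = existence_evidence,
                 gene_names = gene_names),
            class = "protein_record")
}

#' Construct a 3Di record
#'
#' @param accession Accession string.
#' @param tdi_seq 3Di state sequence (uppercased), same length as the paired
#'   amino-acid sequence.
#' @return A list of class `tdi_record`.
#' @export
tdi_record <- function(accession, tdi_seq) {
  structure(list(accession = accession, seq = toupper(tdi_seq)),
            class = "tdi_record")
}

#' Partition records by presence of non-standard residue codes
#'
#' Proteins containing any of B, O, U, Z or X have no predicted structure
#' available and are removed from all datasets.
#'
#' @param records List of `protein_record`s.
#' @return List with `kept` and `dropped`, an exhaustive disjoint partition.
#' @export
filter_standard_residues <- function(records) {
  pattern <- paste0("[", paste(NONSTANDARD_CODES, collapse = ""), "]")
  has_bad <- vapply(records, function(r) grepl(pattern, r$seq), logical(1))
  list(kept = records[!has_bad], dropped = records[has_bad])
}

#' Split a 3Di sequence into overlapping fragments
#'
#' Emulates how structure databases split very long proteins (more than 2700
#' residues) into overlapping windows: every fragment except possibly the
#' last is `window_length` long and consecutive fragments overlap by
#' `overlap` positions (step = `window_length - overlap`).
#'
#' @param accession Accession of the protein.
#' @param seq Full-length 3Di sequence.
#' @param window_length Fragment length in positions (default 1400).
#' @param overlap Overlap between consecutive fragments (default 1200).
#' @return A list of class `fragment_set` with fields `accession`,
#'   `fragments`, `window_length`, `overlap`.
#' @export
split_3di_fragments <- function(accession, seq, window_length = 1400L,
                                overlap = 1200L) {
  if (overlap >= window_length) stop_tp("overlap must be < window_length")
  n <- nchar(seq)
  step <- window_length - overlap
  if (n <= window_length) {
    frags <- seq
  } else {
    starts <- seq.int(1L, n, by = step)
    starts <- starts[starts <= n - overlap]  # last window still adds suffix
    frags <- vapply(starts, function(s) {
      substr(seq, s, min(s + window_length - 1L, n))
    }, character(1))
  }
  structure(list(accession = accession, fragments = as.list(frags),
                 window_length = window_length, overlap = overlap),
            class = "fragment_set")
}

#' Merge overlapping 3Di fragments into one sequence
#'
#' Reassembly starts from the first fragment; each subsequent fragment
#' contributes the suffix after the overlap (positions `overlap + 1` to its
#' end, 1-based). Fragments must agree on the overlapped region.
#'
#' @param fragset A `fragment_set` as built by [split_3di_fragments()] or
#'   constructed manually.
#' @return A `tdi_record` holding the merged sequence.
#' @export
merge_3di_fragments <- function(fragset) {
  frags <- unlist(fragset$fragments)
  overlap <- fragset$overlap
  if (length(frags) == 0L) stop_tp("no fragments to merge")
  merged <- frags[[1]]
  for (i in seq_along(frags)[-1]) {
    frag <- frags[[i]]
    expected <- substr(merged, nchar(merged) - overlap + 1L, nchar(merged))
    observed <- substr(frag, 1L, overlap)
    if (expected != observed) {
      e <- strsplit(expected, "")[[1]]
      o <- strsplit(observed, "")[[1]]
      pos <- which(e != o)[1]
      stop_tp("fragment ", i, " disagrees with the running merge on the ",
              "overlap region, first mismatch at overlap position ", pos)
    }
    merged <- paste0(merged, substr(frag, overlap + 1L, nchar(frag)))
  }
  tdi_record(fragset$accession, merged)
}
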