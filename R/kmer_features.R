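#' k-mer frequency vector of a sequence
#'
#' Counts every overlapping k-mer of a sequence over a 20-letter alphabet and
#' divides by the total number of k-mers, `L - k + 1` (the sequence length
#' for k = 1 and length minus one for k = 2). Feature order is lexicographic
#' over the alphabet so exported matrices are bit-stable.
#'
#' @param seq Sequence string over a 20-letter alphabet.
#' @param k k-mer size, 1, 2 or 3.
#' @param alphabet Character vector of the 20 allowed letters.
#' @return Named numeric vector of length `20^k` summing to 1.
#' @export
kmer_frequencies <- function(seq, k, alphabet = AA_ALPHABET) {
  if (!k %in% 1:3) stop_tp("k must be 1, 2 or 3")
  L <- nchar(seq)
  if (L < k) stop_tp("sequence of length ", L, " is shorter than k = ", k)
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad)) {
    stop_tp("sequence contains characters outside the alphabet: ",
            paste(bad, collapse = ", "))
  }
  kmer_names <- all_kmers(k, alphabet)
  n_win <- L - k + 1L
  windows <- chars[seq_len(n_win)]
  if (k >= 2L) for (j in 2:k) {
    windows <- paste0(windows, chars[seq.int(j, j + n_win - 1L)])
  }
  counts <- table(factor(windows, levels = kmer_names))
  vec <- as.numeric(counts) / n_win
  names(vec) <- kmer_names
  vec
}

# lexicographic k-mer names over the alphabet (assumed already sorted)
#' @noRd
all_kmers <- function(k, alphabet) {
  out <- alphabet
  if (k >= 2L) for (i in 2:k) {
    out <- as.vector(t(outer(out, alphabet, paste0)))
  }
  out
}

# registry: feature id -> (required sequence type, k)
KMER_FEATURES <- list(
  "AAC"       = list(type = "aa",  k = 1L),
  "PAAC"      = list(type = "aa",  k = 2L),
  "AA-KMER3"  = list(type = "aa",  k = 3L),
  "3Di-COMP"  = list(type = "tdi", k = 1L),
  "3Di-KMER2" = list(type = "tdi", k = 2L),
  "3Di-KMER3" = list(type = "tdi", k = 3L)
)

#' Compute a named k-mer feature
#'
#' Dispatches to [kmer_frequencies()] with the alphabet and k implied by the
#' feature id: `AAC`/`PAAC`/`AA-KMER3` encode the amino-acid sequence with
#' k = 1/2/3 and `3Di-COMP`/`3Di-KMER2`/`3Di-KMER3` the structural sequence.
#' Feature names are prefixed with the id so concatenations stay unique.
#'
#' @param feature_id One of `"AAC"`, `"PAAC"`, `"AA-KMER3"`, `"3Di-COMP"`,
#'   `"3Di-KMER2"`, `"3Di-KMER3"`.
#' @param seq_aa Amino-acid sequence, or `NULL`.
#' @param seq_3di 3Di sequence, or `NULL`.
#' @return Named numeric vector, names of the form `<feature_id>.<kmer>`.
#' @export
named_feature <- function(feature_id, seq_aa = NULL, seq_3di = NULL) {
  info <- KMER_FEATURES[[feature_id]]
  if (is.null(info)) stop_tp("unknown feature id: ", feature_id)
  seq <- if (info$type == "aa") seq_aa else seq_3di
  if (is.null(seq)) {
    stop_tp("feature ", feature_id, " requires a ",
            if (info$type == "aa") "amino-acid" else "3Di", " sequence")
  }
  alphabet <- if (info$type == "aa") AA_ALPHABET else TDI_ALPHABET
  vec <- kmer_frequencies(seq, info$k, alphabet)
  names(vec) <- paste0(feature_id, ".", names(vec))
  vec
}

#' Concatenate feature vectors
#'
#' Concatenates already-prefixed feature vectors (e.g., AAC with 3Di-COMP
#' into the 40-position COMB-KMER1 feature), preserving order and values.
#'
#' @param parts Non-empty list of named numeric vectors.
#' @return A single named numeric vector.
#' @export
combine_features <- function(parts) {
  if (length(parts) == 0L) stop_tp("no feature vectors to combine")
  out <- unlist(parts, use.names = FALSE)
  names(out) <- unlist(lapply(parts, names))
  if (anyDuplicated(names(out))) {
    stop_tp("duplicate feature name after concatenation: ",
            names(out)[duplicated(names(out))][1])
  }
  out
}

#' Compute a combined AA + 3Di k-mer feature
#'
#' `COMB-KMER1/2/3` concatenate the amino-acid and 3Di k-mer frequencies of
#' the same k (dimension `2 * 20^k`).
#'
#' @param k k-mer size, 1, 2 or 3.
#' @inheritParams named_feature
#' @return Named numeric vector of length `2 * 20^k`.
#' @export
comb_kmer_feature <- function(k, seq_aa, seq_3di) {
  aa_id <- c("AAC", "PAAC", "AA-KMER3")[k]
  td_id <- c("3Di-COMP", "3Di-KMER2", "3Di-KMER3")[k]
  combine_features(list(named_feature(aa_id, seq_aa = seq_aa),
                        named_feature(td_id, seq_3di = seq_3di)))
}
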