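# Default evidence allowlist: experimental codes plus curated non-electronic
# codes. IEA (inferred from electronic annotation) is always excluded by
# default; fully configurable per dataset.
DEFAULT_EVIDENCE_ALLOWLIST <- c(
  "EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
  "HTP", "HDA", "HMP", "HGI", "HEP",
  "TAS", "IC"
)

#' Parse an OBO 1.2-style ontology file
#'
#' Reads `[Term]` stanzas into a term table and a typed edge list. Obsolete
#' terms are excluded. `is_a` edges are kept apart from all other relation
#' types (`part_of`, `regulates`, ...), because only `is_a` participates in
#' annotation propagation.
#'
#' @param path Path to the OBO file.
#' @return A list of class `go_graph` with `terms` (data.frame: id, name,
#'   namespace) and `edges` (data.frame: from, to, type; child -> parent).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  terms <- list(); edges <- list()
  blocks_end <- c(which(grepl("^\\[", lines)), length(lines) + 1L)
  for (s in starts) {
    e <- min(blocks_end[blocks_end > s]) - 1L
    block <- lines[(s + 1L):e]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ": "), block, value = TRUE)
      if (length(hit)) sub(paste0("^", key, ": "), "", hit[1]) else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) stop_tp("OBO [Term] stanza without an id near line ", s)
    if (identical(get1("is_obsolete"), "true")) next
    terms[[length(terms) + 1L]] <- data.frame(
      id = id, name = get1("name"), namespace = get1("namespace"),
      stringsAsFactors = FALSE)
    for (hit in grep("^is_a: ", block, value = TRUE)) {
      parent <- strsplit(sub("^is_a: ", "", hit), " ! ", fixed = TRUE)[[1]][1]
      edges[[length(edges) + 1L]] <- data.frame(
        from = id, to = trimws(parent), type = "is_a",
        stringsAsFactors = FALSE)
    }
    for (hit in grep("^relationship: ", block, value = TRUE)) {
      fields <- strsplit(sub("^relationship: ", "", hit), "\\s+")[[1]]
      edges[[length(edges) + 1L]] <- data.frame(
        from = id, to = fields[2], type = "other", stringsAsFactors = FALSE)
    }
  }
  terms <- do.call(rbind, terms)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), type = character(0))
  # drop edges to/from obsolete (absent) terms
  edges <- edges[edges$from %in% terms$id & edges$to %in% terms$id, ,
                 drop = FALSE]
  isa <- edges[edges$type == "is_a", , drop = FALSE]
  if (nrow(isa)) {
    g <- igraph::graph_from_data_frame(isa[, c("from", "to")],
                                       vertices = terms$id)
    if (!igraph::is_dag(g)) stop_tp("is_a relation graph contains a cycle")
  }
  structure(list(terms = terms, edges = edges), class = "go_graph")
}

# ancestors (transitive, excluding the term itself) over is_a edges,
# optionally restricted to one namespace
#' @noRd
isa_ancestors <- function(graph, namespace = NULL) {
  terms <- graph$terms
  if (!is.null(namespace)) {
    terms <- terms[terms$namespace %in% namespace, , drop = FALSE]
  }
  isa <- graph$edges[graph$edges$type == "is_a" &
                       graph$edges$from %in% terms$id &
                       graph$edges$to %in% terms$id, , drop = FALSE]
  g <- igraph::graph_from_data_frame(isa[, c("from", "to")],
                                     vertices = terms$id)
  anc <- lapply(terms$id, function(t) {
    setdiff(names(igraph::subcomponent(g, t, mode = "out")), t)
  })
  names(anc) <- terms$id
  anc
}

#' Construct a GO annotation table
#'
#' @param accession,term,evidence_code,qualifier Equal-length vectors; one
#'   annotation per element.
#' @return data.frame with those four columns.
#' @export
go_annotations <- function(accession, term, evidence_code,
                           qualifier = "enables") {
  data.frame(accession = accession, term = term,
             evidence_code = evidence_code,
             qualifier = rep_len(qualifier, length(accession)),
             stringsAsFactors = FALSE)
}

#' Parse a GAF 2.2 annotation file
#'
#' Tab-separated, 17 columns, comment lines starting with `!`. Keeps the
#' accession (column 2), qualifier (4), GO id (5) and evidence code (7).
#'
#' @param path Path to the GAF file.
#' @return Annotation data.frame as from [go_annotations()].
#' @export
parse_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) {
    return(go_annotations(character(0), character(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 15L)
  if (length(bad)) stop_tp("malformed GAF row (", lengths(fields)[bad[1]],
                           " columns) at data line ", bad[1])
  go_annotations(
    accession = vapply(fields, `[[`, character(1), 2L),
    term = vapply(fields, `[[`, character(1), 5L),
    evidence_code = vapply(fields, `[[`, character(1), 7L),
    qualifier = vapply(fields, `[[`, character(1), 4L))
}

#' Propagate annotations to is_a ancestors
#'
#' Every annotation (protein, term) gains annotations (protein, ancestor)
#' for all terms reachable from the annotated term via `is_a` edges, with
#' the evidence code and qualifier inherited from the explicit annotation.
#' Annotations to terms unknown to the graph are skipped with a warning.
#' The operation is idempotent.
#'
#' @param annotations Annotation data.frame ([go_annotations()]).
#' @param graph A `go_graph`.
#' @param namespace Ontology aspect to propagate within (default molecular
#'   function); `NULL` propagates across all namespaces.
#' @return Expanded, de-duplicated annotation data.frame.
#' @export
propagate_annotations <- function(annotations, graph,
                                  namespace = "molecular_function") {
  known <- annotations$term %in% graph$terms$id
  if (any(!known)) {
    warning("skipping ", sum(!known), " annotation(s) to unknown term(s): ",
            paste(unique(annotations$term[!known]), collapse = ", "),
            call. = FALSE)
    annotations <- annotations[known, , drop = FALSE]
  }
  anc <- isa_ancestors(graph, namespace)
  extra <- lapply(seq_len(nrow(annotations)), function(i) {
    up <- anc[[annotations$term[i]]]
    if (is.null(up) || !length(up)) return(NULL)
    data.frame(accession = annotations$accession[i], term = up,
               evidence_code = annotations$evidence_code[i],
               qualifier = annotations$qualifier[i],
               stringsAsFactors = FALSE)
  })
  out <- rbind(annotations, do.call(rbind, extra))
  out <- out[!duplicated(out[, c("accession", "term", "evidence_code",
                                 "qualifier")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter annotations by evidence code and qualifier
#'
#' An annotation is kept iff its evidence code is in the allowlist and its
#' qualifier is not negated (`NOT|...`). The default allowlist contains the
#' experimental and curated non-electronic codes; IEA is excluded.
#'
#' @param annotations Annotation data.frame.
#' @param allowlist Character vector of admissible evidence codes.
#' @return Filtered annotation data.frame.
#' @export
filter_annotations <- function(annotations,
                               allowlist = DEFAULT_EVIDENCE_ALLOWLIST) {
  negated <- grepl("^NOT(\\||$)", annotations$qualifier)
  keep <- annotations$evidence_code %in% allowlist & !negated
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dataset-assembly configuration
#'
#' @param class_terms Named character vector of exactly two GO ids; names are
#'   the class labels.
#' @param evidence_allowlist Evidence codes admitted by
#'   [filter_annotations()].
#' @param identity_threshold Greedy-clustering identity threshold in (0, 1].
#' @param exclude_multilabel Drop proteins annotated with both class terms.
#' @param require_reviewed Keep only manually curated (reviewed) proteins.
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(class_terms,
                           evidence_allowlist = DEFAULT_EVIDENCE_ALLOWLIST,
                           identity_threshold = 0.70,
                           exclude_multilabel = TRUE,
                           require_reviewed = TRUE) {
  if (length(class_terms) != 2L || is.null(names(class_terms))) {
    stop_tp("class_terms must be a named vector of exactly 2 GO ids")
  }
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop_tp("identity_threshold must be in (0, 1]")
  }
  structure(list(class_terms = class_terms,
                 evidence_allowlist = evidence_allowlist,
                 identity_threshold = identity_threshold,
                 exclude_multilabel = exclude_multilabel,
                 require_reviewed = require_reviewed),
            class = "dataset_config")
}

#' Assemble a labeled two-class dataset
#'
#' Labels every protein annotated (after propagation and evidence filtering)
#' with one of the two class terms, excluding proteins that match both
#' classes, sequence fragments, unreviewed entries (if required) and
#' sequences with non-standard residue codes. Per-rule exclusion counts are
#' recorded.
#'
#' @param proteins Named list of `protein_record`s.
#' @param annotations Propagated + filtered annotation data.frame.
#' @param config A `dataset_config`.
#' @return A list of class `labeled_dataset` with `samples` (data.frame:
#'   accession, label), `label_counts`, and `excluded` (accession, reason).
#' @export
assemble_labeled_dataset <- function(proteins, annotations, config) {
  labels <- names(config$class_terms)
  excl <- list()
  note <- function(acc, why) {
    excl[[length(excl) + 1L]] <<- data.frame(accession = acc, reason = why,
                                             stringsAsFactors = FALSE)
  }
  rows <- list()
  for (p in proteins) {
    terms <- annotations$term[annotations$accession == p$accession]
    hits <- labels[config$class_terms %in% terms]
    if (length(hits) == 0L) next
    if (length(hits) == 2L && config$exclude_multilabel) {
      note(p$accession, "multilabel"); next
    }
    if (p$fragment) { note(p$accession, "fragment"); next }
    if (config$require_reviewed && !isTRUE(p$reviewed)) {
      note(p$accession, "unreviewed"); next
    }
    if (grepl(paste0("[", paste(NONSTANDARD_CODES, collapse = ""), "]"),
              p$seq)) {
      note(p$accession, "nonstandard_residues"); next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      accession = p$accession, label = hits[1], stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(accession = character(0), reason = character(0))
  counts <- if (is.null(samples)) integer(0) else table(samples$label)
  for (lb in labels) {
    if (!lb %in% names(counts) || counts[[lb]] == 0L) {
      stop_tp("class '", lb, "' has zero members")
    }
  }
  structure(list(samples = samples, label_counts = counts,
                 excluded = excluded, config = config),
            class = "labeled_dataset")
}

#' Greedy per-class redundancy reduction at a sequence-identity threshold
#'
#' Within each class, sequences are sorted by length (descending, ties by
#' accession) and greedily clustered: a sequence becomes a new cluster
#' representative iff its identity to every existing representative is below
#' the threshold. Identity = exact matches / alignment length of a global
#' pairwise alignment. Only representatives are retained.
#'
#' @param dataset A `labeled_dataset`.
#' @param sequences Named character vector (or list of records) mapping
#'   accession to amino-acid sequence.
#' @param threshold Identity threshold in (0, 1]; defaults to the dataset
#'   config's threshold.
#' @return The reduced `labeled_dataset`.
#' @export
reduce_redundancy <- function(dataset, sequences,
                              threshold = dataset$config$identity_threshold) {
  if (is.list(sequences) && !is.character(sequences)) {
    seqs <- vapply(sequences, function(r) r$seq, character(1))
    names(seqs) <- vapply(sequences, function(r) r$accession, character(1))
    sequences <- seqs
  }
  keep <- character(0)
  for (lb in unique(dataset$samples$label)) {
    accs <- dataset$samples$accession[dataset$samples$label == lb]
    ord <- order(-nchar(sequences[accs]), accs)
    reps <- character(0)
    for (acc in accs[ord]) {
      ok <- TRUE
      for (r in reps) {
        if (sequence_identity(sequences[[acc]], sequences[[r]]) >= threshold) {
          ok <- FALSE; break
        }
      }
      if (ok) reps <- c(reps, acc)
    }
    keep <- c(keep, reps)
  }
  samples <- dataset$samples[dataset$samples$accession %in% keep, ,
                             drop = FALSE]
  rownames(samples) <- NULL
  structure(list(samples = samples, label_counts = table(samples$label),
                 excluded = dataset$excluded, config = dataset$config),
            class = "labeled_dataset")
}

#' Global pairwise sequence identity
#'
#' Identity of a Needleman-Wunsch global alignment: exact matches divided by
#' the alignment length (including gap positions).
#'
#' @param a,b Sequences.
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Export a labeled dataset as TSV (accession, label, status)
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_labeled_dataset <- function(dataset, path) {
  kept <- data.frame(accession = dataset$samples$accession,
                     label = dataset$samples$label, status = "kept")
  dropped <- data.frame(accession = dataset$excluded$accession,
                        label = NA_character_,
                        status = dataset$excluded$reason)
  write.table(rbind(kept, dropped), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
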