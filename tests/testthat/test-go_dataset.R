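# brute-force transitive closure over is_a edges via boolean matrix powers
closure_oracle <- function(graph) {
  ids <- graph$terms$id
  isa <- graph$edges[graph$edges$type == "is_a", , drop = FALSE]
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  A[cbind(isa$from, isa$to)] <- TRUE
  R <- A
  for (i in seq_along(ids)) R <- R | (R %*% A > 0)
  R
}

test_that("parse_obo separates is_a edges and drops obsolete terms", {
  g <- parse_obo(mini_obo_path())
  expect_false("GO:0099999" %in% g$terms$id)  # obsolete
  expect_true("GO:0016020" %in% g$terms$id)
  isa <- g$edges[g$edges$type == "is_a", ]
  other <- g$edges[g$edges$type == "other", ]
  # part_of stored as other, never as is_a
  expect_true(any(other$from == "GO:0008643" & other$to == "GO:0051119"))
  expect_false(any(isa$from == "GO:0008643"))
  # a simple chain is present
  expect_true(any(isa$from == "GO:0022857" & isa$to == "GO:0005215"))
})

test_that("propagation adds exactly the is_a ancestors", {
  g <- parse_obo(mini_obo_path())
  ann <- go_annotations("P1", "GO:0015173", "IDA")
  out <- propagate_annotations(ann, g)
  expect_setequal(out$term,
                  c("GO:0015173", "GO:0015171", "GO:0022857", "GO:0005215",
                    "GO:0003674"))
  # evidence inherited
  expect_true(all(out$evidence_code == "IDA"))

  # root term annotation unchanged
  root <- propagate_annotations(go_annotations("P2", "GO:0003674", "IDA"), g)
  expect_equal(nrow(root), 1L)

  # unknown term skipped with warning
  expect_warning(
    unk <- propagate_annotations(go_annotations("P3", "GO:0099998", "IDA"), g),
    "unknown")
  expect_equal(nrow(unk), 0L)
})

test_that("propagation equals the matrix-power closure oracle (diamond)", {
  g <- parse_obo(mini_obo_path())
  R <- closure_oracle(g)
  # GO:0005351 sits on a diamond (via sugar transporter and via symporter)
  for (t in c("GO:0005351", "GO:0004970", "GO:0015173")) {
    out <- propagate_annotations(go_annotations("PX", t, "IDA"), g)
    expect_setequal(out$term, c(t, names(which(R[t, ]))))
  }
})

test_that("propagation is idempotent and monotone", {
  g <- parse_obo(mini_obo_path())
  ann <- go_annotations(c("P1", "P2"), c("GO:0005351", "GO:0015173"), "IDA")
  once <- propagate_annotations(ann, g)
  twice <- propagate_annotations(once, g)
  expect_setequal(paste(once$accession, once$term),
                  paste(twice$accession, twice$term))
  # adding an annotation never removes propagated terms
  more <- rbind(ann, go_annotations("P1", "GO:0004970", "IDA"))
  out_more <- propagate_annotations(more, g)
  expect_true(all(paste(once$accession, once$term) %in%
                    paste(out_more$accession, out_more$term)))
})

test_that("evidence filtering removes IEA and negated annotations", {
  ann <- parse_gaf(mini_gaf_path())
  expect_equal(ncol(ann), 4L)
  filt <- filter_annotations(ann)
  expect_false("P00008" %in% filt$accession)  # IEA only
  expect_false("P00016" %in% filt$accession)  # IEA only
  expect_false("P00012" %in% filt$accession)  # NOT|enables
  expect_true("P00001" %in% filt$accession)   # IDA kept
  expect_true("P00018" %in% filt$accession)   # HDA kept (high-throughput)
})

test_that("assemble_labeled_dataset applies labels and exclusion rules", {
  g <- parse_obo(mini_obo_path())
  ann <- filter_annotations(parse_gaf(mini_gaf_path()))
  expect_warning(prop <- propagate_annotations(ann, g), "unknown")
  proteins <- list(
    P00001 = protein_record("P00001", random_seq(40, 1)),
    P00002 = protein_record("P00002", random_seq(40, 2)),
    P00003 = protein_record("P00003", random_seq(40, 3)),
    P00004 = protein_record("P00004", random_seq(40, 4)),
    P00005 = protein_record("P00005", random_seq(40, 5)),
    P00006 = protein_record("P00006", random_seq(40, 6)),
    P00007 = protein_record("P00007", random_seq(40, 7)),
    P00009 = protein_record("P00009", random_seq(40, 9)),   # both classes
    P00011 = protein_record("P00011", random_seq(40, 11), fragment = TRUE),
    P00013 = protein_record("P00013", random_seq(40, 13), reviewed = FALSE),
    P00014 = protein_record("P00014", paste0(random_seq(40, 14), "X")),
    P00017 = protein_record("P00017", random_seq(40, 17)),  # neither class
    P00018 = protein_record("P00018", random_seq(40, 18))
  )
  cfg <- dataset_config(c(amino = "GO:0015171", sugar = "GO:0051119"))
  ds <- assemble_labeled_dataset(proteins, prop, cfg)
  # amino: P00001 P00002 P00003(descendant) P00004; sugar: P00005-7, P00018
  expect_equal(as.vector(ds$label_counts[c("amino", "sugar")]), c(4L, 4L))
  # P00006 included via propagation from a descendant term
  expect_true("P00006" %in% ds$samples$accession)
  reasons <- stats::setNames(ds$excluded$reason, ds$excluded$accession)
  expect_equal(unname(reasons["P00009"]), "multilabel")
  expect_equal(unname(reasons["P00011"]), "fragment")
  expect_equal(unname(reasons["P00013"]), "unreviewed")
  expect_equal(unname(reasons["P00014"]), "nonstandard_residues")
  expect_false("P00017" %in%
                 c(ds$samples$accession, ds$excluded$accession))

  # the faulty channel-under-transporter edge pulls GLR33 into the class:
  # propagation follows the graph as given (outlier detection mitigates)
  ds2 <- assemble_labeled_dataset(
    c(proteins, list(P00010 = protein_record("P00010", random_seq(40, 10)))),
    prop, cfg)
  expect_true("P00010" %in%
                ds2$samples$accession[ds2$samples$label == "amino"])

  # a class with zero members errors
  cfg0 <- dataset_config(c(amino = "GO:0015171", none = "GO:0016020"))
  expect_error(assemble_labeled_dataset(proteins, prop, cfg0), "none")
})

test_that("reduce_redundancy retains no pair above the threshold", {
  base <- random_seq(120, seed = 21)
  mutate <- function(seq, n_mut) {
    ch <- strsplit(seq, "")[[1]]
    idx <- sample(length(ch), n_mut)
    ch[idx] <- sample(aa_letters, n_mut, replace = TRUE)
    paste(ch, collapse = "")
  }
  # identical pair collapses to one
  seqs <- c(A1 = base, A2 = base)
  ds <- structure(list(samples = data.frame(accession = c("A1", "A2"),
                                            label = "x"),
                       excluded = data.frame(), config = NULL),
                  class = "labeled_dataset")
  red <- reduce_redundancy(ds, seqs, threshold = 0.7)
  expect_equal(nrow(red$samples), 1L)

  # pair with identity below threshold: both retained
  set.seed(22)
  far <- c(B1 = base, B2 = random_seq(120))
  expect_lt(sequence_identity(far[["B1"]], far[["B2"]]), 0.7)
  ds2 <- structure(list(samples = data.frame(accession = c("B1", "B2"),
                                             label = "x"),
                        excluded = data.frame(), config = NULL),
                   class = "labeled_dataset")
  expect_equal(nrow(reduce_redundancy(ds2, far, threshold = 0.7)$samples), 2L)

  # family fixture: mutated copies of 3 seeds; brute-force all-pairs check
  set.seed(11)
  seeds <- replicate(3, random_seq(100))
  fam <- unlist(lapply(1:3, function(s) {
    vapply(1:6, function(i) mutate(seeds[s], sample(2:8, 1)), character(1))
  }))
  names(fam) <- sprintf("F%02d", seq_along(fam))
  ds3 <- structure(list(samples = data.frame(accession = names(fam),
                                             label = "x"),
                        excluded = data.frame(), config = NULL),
                   class = "labeled_dataset")
  red3 <- reduce_redundancy(ds3, fam, threshold = 0.7)
  kept <- red3$samples$accession
  expect_lte(length(kept), 3L)
  if (length(kept) > 1) {
    pairs <- utils::combn(kept, 2)
    for (p in seq_len(ncol(pairs))) {
      expect_lt(sequence_identity(fam[[pairs[1, p]]], fam[[pairs[2, p]]]),
                0.7)
    }
  }
  # output is a subset of input
  expect_true(all(kept %in% names(fam)))
})
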