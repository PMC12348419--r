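---
title: "Predicting transporter substrates from sequence and structure encodings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transporter substrates from sequence and structure encodings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpred)
```

## Scope and model

`transpred` classifies membrane transport proteins into two substrate
classes from fixed-length numerical encodings of their amino-acid
sequence, their 3Di structural-state sequence, their evolutionary
conservation profile, or pooled per-residue embeddings. The package covers
the full workflow — labeled-dataset construction from ontology
annotations, feature encoding, consensus outlier screening, and two
classifiers evaluated under a repeated nested cross-validation protocol —
and ships synthetic generators so every stage runs offline.

The computation of the raw inputs themselves is out of scope by design:
3Di sequences are consumed as FASTA (they come from a structure-to-3Di
converter run on predicted structures), PSSMs are consumed as the ASCII
output of an iterative homology search, and per-residue embeddings are
consumed from a keyed container. The package neither predicts structures
nor runs language models or homology searches.

## Feature encoders

**k-mer frequencies.** A sequence over a 20-letter alphabet maps to the
vector of overlapping k-mer counts divided by `L - k + 1` (the sequence
length for k = 1, length minus one for k = 2). Dimensions are
`20^k`: 20, 400, 8000. The same operation applied to the 3Di alphabet
gives the structural compositions (3Di-COMP/-KMER2/-KMER3), and
AA + 3Di concatenations of equal k give the COMB features (40, 800,
16000). Feature names are fixed lexicographically and prefixed with their
feature id so concatenations never collide and exported matrices are
byte-stable.

Sequences shorter than k are an error rather than a zero vector: a silent
zero vector would violate the per-block sums-to-one invariant that the
tests rely on.

**Conservation profiles.** An iterative profile search yields an n×20
integer log-odds matrix per protein. For each amino-acid type the rows at
positions carrying that type are averaged, giving a 20×20 profile; residue
types absent from the sequence get zero rows (the natural "no evidence"
value — the alternative, dropping rows, would make the dimension depend on
the sequence). Four profiles, from two databases × two iteration counts,
are flattened row-major and concatenated in the fixed order uniref50/1,
uniref50/3, uniref90/1, uniref90/3 into the 1600-dim Multi-PSSM. The
block order is a documented convention; any fixed order works, but it must
never change across runs. Only the log-odds block of the ASCII file is
used, not the frequency block.

**META and META-STD.** META is the plain concatenation
AAC | PAAC | Multi-PSSM (2020 dims). META-STD z-scores each block within
each sample before concatenating, so no statistic is shared between
samples; it should be read as a per-protein fingerprint, since per-sample
standardization distorts scales along feature dimensions. A constant
block maps to zeros (division-by-zero guard). The two features are kept
distinct — only the STD variant is standardized — so that they can behave
differently downstream.

**Embedding pooling.** Per-residue embedding matrices (n×d, d typically
1024) are mean-pooled over *all* residue positions. The alternative
reading "average embedding per token type" would produce a 20×d object,
contradicting the d-dimensional per-protein representation everywhere
else, so plain mean pooling is used.

**Dummy feature.** 1024 draws from U(0,1), seeded from a stable
31-polynomial hash of the accession mixed with a global seed. Hashing the
accession (rather than consuming a shared RNG stream) makes the vector
independent of dataset order, which is what "deterministically drawn"
has to mean for reproducible experiments. Its role is calibration: any
model×protocol combination that scores clearly above chance on this
feature is leaking information.

## Dataset construction from ontology annotations

Annotations (GAF 2.2) are filtered to an evidence allowlist — the
experimental codes EXP/IDA/IPI/IMP/IGI/IEP, their high-throughput
variants, and the curated codes TAS/IC; electronic annotations (IEA) are
excluded by default, and negated ("NOT") qualifiers are always dropped
since keeping them would invert labels. Annotations then propagate
upward along `is_a` edges of the ontology graph (molecular-function
namespace by default); `part_of` and other relation types are stored but
never used for propagation. Propagation is idempotent and monotone, and
is tested against a boolean matrix-power reachability oracle.

A labeled two-class dataset keeps every protein annotated, after
propagation, with exactly one of the two class terms; proteins matching
both are excluded (too few to form a third class), as are fragments,
unreviewed entries (configurable), and sequences with non-standard
residue codes (B, O, U, Z, X — these have no predicted structures).
Within each class, greedy clustering at 70% identity (exact matches over
global-alignment length, longest-first, ties by accession) keeps only
cluster representatives, so near-duplicate sequences cannot straddle a
train/test split. The internal clustering replaces an external tool so
tests run offline; its identity definition (alignment-length denominator)
differs subtly from word-based tools, which is why it is documented here.

The ontology fixture shipped with the package deliberately contains a
wrong `is_a` edge (a glutamate-gated ion channel filed under amino-acid
transmembrane transporters, mirroring a real ontology defect). The
dataset builder follows the graph as given — a test documents that the
mislabeled protein enters the dataset — and the outlier module is the
intended mitigation.

## Outlier detection, and what it can and cannot find

Each feature dataset is z-scored, projected onto the smallest number of
principal components reaching 95% cumulative explained variance, and
scored by an isolation forest (100 trees, subsample min(256, n), depth
cap ⌈log2 ψ⌉). A sample scoring above the conventional automatic
threshold of the normalized path-length score (0.5) is flagged; samples
flagged in at least 50% (inclusive) of feature datasets are consensus
outliers. Outlier removal is an optional dataset-construction step and is
never invoked inside cross-validation, because it would use test-fold
information; the evaluation entry point does not even expose an outlier
argument.

A limitation worth stating precisely, because a test encodes it: a point
displaced along a *single* direction — however far — is largely invisible
to this pipeline at moderate magnitudes. PCA rotates the displacement
into one retained component, the point is perfectly central in all other
components, and isolation forests are invariant to per-column affine
scaling, so the remaining components act as camouflage. Simulation (and
the scikit-learn reference stack, which agrees with this implementation
to two decimals on shared data) shows single-direction displacements of
10 column-SDs are not flagged at n = 50, d = 30, while displacements
large enough that the first component alone approaches the 95% target
(≈ 50 SDs) are recovered on every seed. Real outliers — wrong-class
proteins, β-barrel pores among α-helical carriers — deviate in many
directions at once across several feature datasets, which is the case
the consensus rule is designed for. One acceptance test asserts the
10-SD single-direction recovery as originally specified and is expected
to fail; it is kept red rather than weakened.

## Classifiers

**SVM pipeline.** Per candidate (k, C): drop zero-variance training
columns, keep the k highest ANOVA F-scores (F = between-class over
within-class variance ratio; ties broken lexicographically by feature
name so selection is deterministic), z-score the selected columns, and
train a weighted C-SVC with RBF kernel. The kernel width is
γ = 1 / (var(X)·m) with var the pooled variance of all entries of the
matrix as passed to the kernel — i.e., after standardization, making γ
effectively 1/m; computing it pre-standardization would only rescale the
same heuristic. Class weights n/(K·n_i) multiply C per sample, so both
classes carry equal total weight. k ranges over {10, 25, 50, 100, 200}
truncated to min(200, m′) — the candidate list is a package choice, the
cap is prescribed — and C over {0.1, 1, 10}. Candidates are scored by
mean balanced accuracy over a stratified 5-fold inner cross-validation;
ties prefer the smallest k, then the smallest C (the simpler model). The
solver is a maximal-violating-pair SMO on the standard dual,
implemented in-package because no SVM library is available in the target
environment; at the package's dataset sizes (tens to low hundreds of
samples) it converges in milliseconds.

**FNN.** Input → 512 → ReLU → dropout(0.5) → 256 → ReLU → dropout(0.5) →
128 → ReLU → dropout(0.5) → 1 → sigmoid, trained with Adam (step 0.001 —
the conventional default, as no learning rate is prescribed) on binary
cross-entropy, batch 8, 50 epochs, no early stopping and no inner
hyperparameter search; dropout is the only regularizer. "Interspersed
with dropout" is read as one dropout layer after each hidden layer and
none on the input. Inference uses the strict rule p > 0.5 → positive, so
p = 0.5 exactly is negative. The positive class is the second sorted
label level. Class weighting is applied only in the SVM, which is where
it is specified. Preprocessing for the FNN is the zero-variance filter
plus z-scoring (no ANOVA selection; the network sees every informative
column). Determinism is per machine given the seed; bit-identical
training across BLAS builds is not promised.

## Evaluation protocol

Stratified 5-fold assignment deals each shuffled class round-robin into
folds, so per-fold class counts are the floor or ceiling of
proportionality and a 54-sample 26/28 dataset yields test folds of 10–11.
Five repetitions reshuffle with seeds master_seed + 1 … + 5; fold
assignment depends only on the labels and the seed, so every feature
evaluated under one master seed sees identical splits. Each outer
training split runs the SVM's inner grid search (the FNN path skips it),
refits on the whole split, and scores the held-out fold: 25 rows of
balanced accuracy (mean per-class recall — exactly 1/K for any constant
predictor), per-class F1 (zero-division convention: an unpredicted class
has precision 0 and F1 0) and macro F1. Aggregates use the sample (n−1)
standard deviation. "Best parameters across the five inner splits" is
interpreted as the candidate with the highest mean inner score, the
standard nested-CV reading.

## Synthetic data: what it emulates, what it does not

The generator draws, per class, a residue distribution from a Dirichlet
centred on a tilted uniform: mean frequency ∝ (1 + δ·s) with s = ±1 on
alternating letter blocks, sign flipped between classes and phase-shifted
between the AA and 3Di channels; per-protein compositions are then
Dirichlet draws (concentration 50·20 about the class mean, within-class
variability a scientist would call family-level spread) and residues are
i.i.d. At δ = 0 the two classes' generators are identical — a chi-square
test across 20 seeds confirms indistinguishability — and downstream
scores sit in the chance band. Defaults (26/28 samples, lengths 200–800,
δ = 0.3) mirror the size and split of the two-class carrier benchmark and
typical transporter lengths; δ = 0.3 was calibrated once by a sweep as
the smallest grid value at which both classifiers reach balanced
accuracy ≥ 0.95, and is not revisited. Synthetic PSSMs add a diagonal
conservation bonus and a class shift on the log-odds scale; synthetic
embeddings place class means ±signal apart along one random direction
with unit isotropic noise.

What the generator does *not* emulate: positional motifs, domain
architecture, phylogenetic correlation between samples, alignment-based
redundancy structure, or any real biology. A green test therefore
establishes that the pipeline's machinery (encoders, selection,
training, protocol bookkeeping) is correct and leak-free — not that any
particular feature family will win on real transporters.

## Numerical choices and degenerate inputs

* k-mer vectors: lexicographic feature order; error (not zero vector) for
  sequences shorter than k.
* Conservation profiles: zero rows for absent residue types.
* META-STD: constant blocks map to zeros.
* ANOVA F: 0/0 columns (constant within and across classes) score 0; a
  positive between-class difference with zero within-class variance
  scores Inf and sorts first, which is the desired behaviour.
* γ: error on zero pooled variance rather than a silent fallback.
* SMO: tolerance 1e-3 on the maximal KKT violation, iteration cap 1e5;
  bias from free support vectors, else the bound midpoint.
* Isolation forest: subsample without replacement; truncated paths are
  compensated with the average-unsuccessful-search term c(size).
* Fragment merging is 1-based: "suffix after position 1200" means
  positions 1201 … end; each non-final 1400-window contributes 200 new
  positions. Split-then-merge is the identity for every valid
  (window, overlap) pair, which the property tests exercise.
* Dummy-feature hashing keeps all arithmetic below 2^53 so the seed is
  exact in doubles on every platform.

## Known limitations

* Single-direction planted outliers at moderate magnitude are
  undetectable after the PCA step (see above); this is a property of the
  prescribed pipeline, shared by the reference implementation.
* The SMO solver and pure-R network are sized for desk-scale datasets
  (≲ a few hundred samples); they are not replacements for large-scale
  libraries.
* Multi-class tasks are out of scope; the three ion-channel comparisons
  of the motivating application are three binary datasets.
* External adapters (structure-to-3Di conversion, homology search,
  embedding inference, live annotation downloads) are intentionally not
  implemented; their outputs are file-format contracts that the synthetic
  generators emulate.
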