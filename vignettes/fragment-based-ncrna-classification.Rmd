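---
title: "Fragment-based classification of non-coding RNA secondary structures"
author: "rnaFragNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based classification of non-coding RNA secondary structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaFragNet)
```

## The model

Non-coding RNA classes are defined largely by what the molecule folds
into, not by its primary sequence. rnaFragNet operationalises this in
three stages.

**Structure graphs.** A record is a sequence over the normalized alphabet
A/C/G/U/N together with a dot-bracket structure of equal length, as
emitted by a secondary-structure predictor. Extended bracket families
(`()`, `[]`, `{}`, `<>` and `A`–`Z` with `a`–`z`) are matched by
independent per-family stacks, so crossing pair sets (pseudoknots) parse
naturally. The graph has one vertex per position, labelled with the base;
covalent `backbone` edges join consecutive positions and one `pair` edge
joins each base pair. Both edge kinds are kept, with distinct bond
labels: mined fragments may then span stem *and* loop context, which is
what makes hairpin signatures expressible. A structure that pairs
adjacent bases is rejected as geometrically impossible. Positions are
1-based everywhere (R convention), including in the serialized formats.

**Closed frequent sub-graph mining.** The support of a fragment —
a connected labelled graph — is the number of records whose graph
contains at least one label- and bond-preserving sub-graph isomorphic
embedding of it; multiplicity within one record is deliberately ignored,
so a long poly-A stretch does not inflate the support of A–A. Matching is
sub-graph, not induced-sub-graph, isomorphism: a fragment may omit edges
present between its nodes in the host. Given a support percentage σ over
g graphs the absolute threshold is ⌈σ·g/100⌉ (an "at least" reading of
minimum frequency), and fragment size is counted in **nodes**
(nucleotides), which is the convention under which size windows such as
2/4 or 3/6 are meaningful. Only *closed* fragments are reported — no
one-edge extension has equal support — which removes the redundancy of
reporting every sub-fragment of a conserved motif at identical support.
Closedness is evaluated within the size window: extensions that would
exceed the maximum size are not considered, mirroring a search truncated
at that size. The closed set is threshold-independent in the sense that
raising σ only removes fragments, a property the test suite exercises.

The miner grows fragments depth-first from single-node seeds by one-edge
extensions (a new node, or an extra edge between existing nodes),
carrying complete embedding lists downward and pruning duplicates with a
canonical code (lexicographically minimal serialization over
refinement-constrained node orderings). Embeddings are stored over a
disjoint union of all host graphs, which keeps candidate generation
vectorised. Because every step is deterministic and the output is sorted
by (size, canonical code), identical inputs yield byte-identical fragment
files. An independent brute-force oracle (`oracleMineFragments()`,
exhaustive enumeration of connected edge subsets, capped at 10 nodes per
graph) implements the same contract and is compared against the miner on
randomized instances in the tests.

**Boolean features and the frozen space.** The feature matrix sets
A(i, j) = 1 iff fragment j is contained in graph i. For the graphs that
were mined, containment is already known from the embedding lists
(`miningFeatureMatrix()`); for new graphs it is recomputed by an exact
backtracking matcher with label/degree pruning (`projectGraphs()`).
Projection never re-mines: the fragment list and its column order are
frozen at training time, absent fragments simply give 0, and projecting
the training graphs reproduces the training matrix bit for bit.

## The classifier

The network is intentionally small: two convolutional layers with
logistic activations and width-2 max-pooling, then a one-hidden-layer
perceptron. For input length L and kernel width k, valid (no-padding,
stride-1) cross-correlation gives per-kernel outputs of length L − k + 1;
pooling floors to ⌊·/2⌋, dropping a trailing odd element. With the
default widths 5/5 and 20 second-layer kernels, L = 6443 features chain
through 6439 → 3219 → 3215 → 1607 and flatten to 32 140 values. The
flattened vector feeds `hidden` tanh units and a softmax output; training
minimises the categorical cross-entropy by mini-batch SGD. Since the
inputs are binary, a width-5 window can realise at most 2⁵ − 1 = 31
distinct nonzero patterns, which bounds how many first-layer kernels can
detect genuinely different configurations; the defaults (n1 = 10,
n2 = 20, 500 hidden units, pool 2) stay below that bound.

Choices the architecture description leaves open, fixed here:

* **Second kernel width** is 5 by default (the evaluated configuration),
  exposed as `k2` in `cnnConfig()`.
* **Hidden activation** is tanh; the logistic is applied to convolution
  outputs, before pooling.
* **Convolution** means cross-correlation (no kernel flip) — equivalent
  in capacity, fixed for reproducibility.
* **Odd-length pooling** drops the trailing element, applied
  consistently in forward and backward passes.
* **Loss/optimisation defaults**: cross-entropy, learning rate 0.1,
  batch 20, 200 epochs, per-epoch reshuffling; all overridable, all
  seeded, so identical seeds give bit-identical models.
* **Initialisation.** Biases start at zero. First-layer kernels start
  uniform in ±1: with 0/1 inputs and small fan-in-scaled kernels, the
  sigmoid-plus-max-pool stack produces activations that are almost
  constant across samples (the pooled maximum is decided by the weights,
  not the input), the flattened representation carries vanishing sample
  variance, and SGD stalls at the class prior. Unit-range first-layer
  kernels spread the pre-activations across the responsive range of the
  logistic and remove the stall. Deeper layers use uniform weights scaled
  down by fan-in (±√(6/fan-in) for the second convolution, ±1/√fan-in for
  the perceptron). This was diagnosed and chosen on training-set
  behaviour of the optimisation alone.
* **Ties** in prediction resolve to the lowest class index; analytic
  gradients are verified against central finite differences in the test
  suite (relative error below 1e-4 on a small network).

Models serialize to a single JSON archive (config, class order, frozen
fragment codes, weight arrays with shapes at 17 significant digits), so a
reloaded model predicts bit-exactly.

## Evaluation protocol

`stratifiedFolds()` shuffles each class with the given seed and deals
records round-robin, so per-class fold sizes differ by at most one.
`crossValidate()` then, per fold: mines fragments on the training portion
only, builds the training matrix from the mining supports, trains the
network (fold index offsets the seed), projects the held-out records into
that fold's frozen feature space, and predicts. The reported confusion
matrix is the elementwise sum of the fold matrices, and the statistics
are computed from the summed matrix. The implementation asserts that no
fragment's supporting ids reference a held-out record — re-mining per
fold is the leakage-free reading of the protocol, and the package always
does it.

Statistics are one-vs-rest per class: accuracy, sensitivity TP/(TP+FN),
specificity TN/(TN+FP), precision TP/(TP+FP), F-score 2TP/(2TP+FP+FN),
and the Matthews correlation coefficient, macro-averaged without weights
(the intended datasets are near-balanced). The trace/total accuracy is
reported alongside, because macro one-vs-rest accuracy and plain
fraction-correct answer different questions; both appear in the metrics
file. Multi-class MCC is the macro average of the per-class binary MCCs,
matching the one-vs-rest reduction used for the other five statistics.
A statistic with a zero denominator (possible only in degenerate folds)
is reported as 0 with a warning rather than NaN.

## The synthetic data generator

`generateDataset()` emulates the essential property of a curated
multi-class ncRNA set — several structurally distinct classes — without
any downloads. Class c's signature is a hairpin with a stem of 3 + c base
pairs whose pair sequence cycles through {GC, CG, AU, UA, GU} with a
class-specific phase, closed by a class-specific loop trinucleotide,
embedded at a seeded-random offset inside random unpaired flanks of
25–40 nt (default). Structures are emitted as the ground-truth pairing of
the embedded motif, so the feature signal is controlled; the toy folder
`toyFold()` (base-pair maximization with Watson–Crick + GU pairs, minimum
loop 3, deterministic leftmost-pairing traceback) exists separately to
exercise the FASTA-only input path and is validated against exhaustive
enumeration on short sequences. Substitution noise (`mutationRate`)
perturbs the sequence only, leaving the structure string untouched — a
simple model of predictor/sequence mismatch.

What passing the end-to-end test shows, and what it does not: with no
noise the class motifs are frequent, mineable, and perfectly
discriminative, so 10-fold cross-validation of the 5 × 40 dataset
(support 10%, sizes 2–6) recovering ≥ 0.9 macro accuracy demonstrates
that every stage — parsing, mining, projection, training, evaluation —
composes correctly. It does not demonstrate real-Rfam performance: real
classes overlap structurally, structures come from an imperfect
predictor, and class sizes are larger; accuracy there is an empirical
question outside this package's data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale problems
chosen once: random graphs of 4–8 nodes for miner-vs-oracle equivalence
(100 sets), the 200-record synthetic dataset for cross-validation with
`hidden = 64`, `epochs = 40` (the feature space there is ~630 fragments,
so a 500-unit hidden layer is unnecessary capacity; mining parameters
follow the protocol above), and a tiny network (L = 12, n1 = n2 = 2,
hidden = 5) for the gradient check. `crossValidate()` reduces kernel
widths automatically when a fold's mined feature space is narrower than
the configured kernels — relevant only for toy examples.

Known limitations: the miner is exact and therefore exponential in the
worst case (dense, highly symmetric graphs); RNA structure graphs are
sparse (degree ≤ 3) and the size window small, which keeps it fast in
practice. Canonicalisation refuses pathologically symmetric fragments
(beyond ~8! constrained orderings), which cannot arise from RNA graphs
within the default size window. `N` matches only `N` during mining — no
wildcard semantics — so degenerate IUPAC codes neither create nor join
fragments. CT/BPSEQ input and approximate matching are out of scope.
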