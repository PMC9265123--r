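---
title: "Classifying cancer types from chromosomal rearrangement graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cancer types from chromosomal rearrangement graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromgraph)
```

## The problem and the data model

Structural chromosomal aberrations — translocations, deletions, inversions,
duplications, insertions — are found in essentially every analyzed cancer
genome, and their endpoint patterns differ between tumor types. This package
asks whether the *chromosome-level wiring* of a tumor's rearrangements, with
all within-chromosome positional detail discarded, carries enough signal to
classify its cancer type.

The input is a breakpoint table in the style of COSMIC structural-variant
exports: one row per aberration, with a sample name, a cancer-type label
(primary site), a mutation type, and two breakpoint locations
(`"Location From"`, `"Location To"`) of the form `chrom:start..end`. Seven
mutation types occur: inverted orientation, noninverted orientation,
inversion, deletion, tandem duplication, insertion, and unknown.
Interchromosomal events (interCAs) are always reported with the unknown
type; only intrachromosomal events (intraCAs) carry one of the six typed
calls. `read_breakpoints()` normalizes chromosome tokens onto the fixed
universe of 24 nodes (autosomes 1–22, X = 23, Y = 24); mitochondrial and
unplaced contigs are rejected row-wise and counted rather than raising
errors, because real exports contain them. Breakpoint coordinates are
parsed and retained but never used downstream — only chromosome identity
matters to the model.

Every sample becomes one **directed multigraph** on those 24 nodes: each
aberration adds an edge from its source chromosome to its sink chromosome,
repeated aberrations give parallel edges, and intraCAs give self-loops.
Duplicate rows are retained deliberately: under multigraph semantics the
multiplicity of a rearrangement is information, not noise.

## Average connectivity and filtering

Samples with very few aberrations produce sparse, nearly edgeless graphs
that carry little signal. To score how informative a graph is we use the
average connectivity

$$\bar\kappa(G) \;=\; \frac{\sum_{u<v} \kappa_G(u,v)}{\binom{p}{2}},
\qquad p = 24,$$

where $\kappa_G(u,v)$ is the maximum number of pairwise **edge-disjoint**
paths joining chromosomes $u$ and $v$. By Menger's theorem this equals the
minimum number of edges separating $u$ from $v$, and is computed as
unit-capacity maximum flow with BFS augmenting paths (Edmonds–Karp). All
$\binom{24}{2} = 276$ unordered pairs enter the denominator whether
adjacent or not, so a single-edge graph scores exactly $1/276 \approx
0.0036$ and the complete simple graph on 24 nodes scores 23.

Three conventions are worth making explicit:

* **Edge-disjoint, not node-disjoint.** Disjointness is defined by paths
  never sharing an edge; an internally node-disjoint variant is available
  via `node_disjoint = TRUE` (standard node-splitting construction) for
  sensitivity analysis, and is provably never larger.
* **Symmetrization.** The average runs over unordered pairs, so
  $\kappa$ is computed on the underlying undirected multigraph: each
  directed edge contributes one unit of undirected capacity, parallel
  edges add up. Edge direction is preserved only for the classifier.
* **Self-loops contribute nothing** — they can never lie on a $u$–$v$
  path. An intra-only graph therefore always has $\bar\kappa = 0$, which
  is why filtering is *always* computed on the integrated (inter + intra)
  graph even when the classifier is later restricted to one edge class;
  filtering on the intra-restricted graph would empty that experiment.

For all-pairs computation, `pairwise_connectivity()` builds a Gomory–Hu
tree with Gusfield's algorithm: 23 max-flow calls yield every pairwise
value at once (the minimum edge weight on the tree path between $u$ and
$v$), which on a dense cohort is roughly an order of magnitude cheaper
than 276 per-pair flows. The direct per-pair method remains available via
`method = "direct"` and the test suite asserts the two are identical on
random multigraphs; a third, exponential-time exhaustive oracle
(`brute_force_disjoint_paths()`, capped at 10 edges) anchors both.

Filtering keeps a graph when $\bar\kappa \ge \tau$ with $\tau = 0.3$ by
default — the operative threshold reported for this method. The
comparison is inclusive at the boundary. Because the source literature
also mentions removing *very dense* graphs, an optional upper threshold
`tau_high` is exposed but off by default; the sparse-removal reading is
the primary one.

## The classifier

The classifier is a graph attention network (GAT) for graph-level
prediction. Node $u$'s embedding is updated by aggregating its
in-neighborhood $\xi(u)$:

$$m_{\xi(u)} = \sum_{v \in \xi(u)} \alpha_{u,v}\, W h_v,$$

with attention coefficients $\alpha_{u,v}$ softmax-normalized over
$\xi(u)$ and scored by a LeakyReLU of learned source/destination
projections, following the standard GAT construction (the aggregation
rule fixes only the weighted sum; the scoring internals are the cited
construction's). Design choices the architecture leaves open, and what
this package does:

* **Node features.** The attribute matrix defaults to the adjacency rows
  (`adjacency_row`, $d = 24$): row $u$ holds the counts of edges
  $u \to w$. A richer scheme (`adjacency_row_plus_types`, $d = 31$)
  appends the per-node count vector of self-loop mutation types, which is
  informative exactly where typed calls exist. The scheme is recorded in
  every checkpoint. Chromosome identity is implicit in row order and not
  one-hot encoded — adjacency rows already individuate nodes.
* **Self-loops for message passing.** Every node receives a self-loop in
  the message-passing edge list so each chromosome retains its own state
  across layers.
* **Multiset neighborhoods.** A neighbor connected by $k$ parallel edges
  appears $k$ times in the softmax, letting aberration multiplicity pull
  attention mass; `dedup_neighborhoods = TRUE` switches to deduplicated
  neighborhoods.
* **Depth.** `n_hubs` stacked layers give each chromosome an $n$-hop
  receptive field; the default is 6, the depth reported to perform best
  for this method. `hub_sweep()` retrains across a depth range at a fixed
  seed. One caveat discovered while designing tests: with adjacency-row
  features, any difference between two edge multisets is already visible
  to a depth-1 model after pooling, so clean depth *separations* cannot
  be constructed synthetically — the sweep test asserts non-inferiority
  of deeper models on chain-structured signal, not superiority.
* **Readout and head.** Coordinate-wise global max pooling over the 24
  node embeddings (invariant to node order), then a dense layer and
  log-softmax. ELU nonlinearities follow each aggregation.
* **Loss.** Multiclass negative log likelihood on the log-softmax
  outputs. (The source's loss equation is typeset in binary
  cross-entropy notation while the text specifies NLL on log-softmax; the
  text's reading is implemented.)
* **Imbalance.** Per-class weights proportional to inverse class counts,
  rescaled to mean 1, drive sampling-with-replacement of each epoch's
  batches, so expected batch composition is uniform across classes. A
  chi-square test over 10,000 draws confirms this empirically.
* **Optimization.** Adam, learning rate 0.001, batch size 10, at most
  200 epochs, dropout 0.2 on node embeddings between layers; no early
  stopping. Hidden width (default 64) and head count (default 1,
  concatenated when more) are free parameters recorded in the model.

The forward and backward passes are implemented directly in R, batched by
stacking graphs block-diagonally (node rows offset by 24 per graph) so
edgewise operations vectorize across the batch. The backward pass is
hand-derived; the test suite verifies it against central finite
differences and checks gradient flow end-to-end by overfitting random
labels. All randomness — initialization, batch sampling, dropout —
derives from the configured seed, so training histories are bitwise
reproducible on one machine.

### Baselines

The comparison harness runs flat per-aberration classifiers on a one-hot
encoding (source chromosome + sink chromosome + mutation type, 55
columns): a feed-forward network (three hidden ReLU layers of 60 units),
linear and polynomial SVMs (via e1071), and kNN with Euclidean, Minkowski
or Mahalanobis distance (ridge-whitened — the one-hot blocks make the raw
covariance singular). Splits are always by sample, never by row, to avoid
leakage between aberrations of one tumor. Whether evaluation should count
aberrations or samples is genuinely ambiguous in the source (its support
counts suggest aberrations); both units are implemented and every report
states its unit. The interesting property, reproduced as a test, is
*why* the graph model wins: on cohorts whose class signal lives only in
the co-occurrence of aberrations within a sample — with single-aberration
marginals identical across classes — flat per-aberration models are
pinned near chance while the graph model is not.

## The synthetic cohort generator

No public download is assumed, so the generator emulates the data model
end-to-end: per class, an interchromosomal signature (probability mass
over ordered chromosome pairs), an intraCA rate, a typed-mutation
distribution for intraCAs, a negative-binomial aberration count per
sample, and a uniform background mixed in at `background_rate`. InterCAs
are always emitted with the unknown mutation type, mirroring the
catalogue convention, so the typed feature scheme behaves as on real
exports. The default `intra_rate = 0.75` echoes the roughly 3:1
intra:inter ratio seen in real catalogues.

`make_separable_cohort()` is the reference fixture: three classes with
disjoint two-pair signatures (1–2/3–4, 5–6/7–8, 9–10/11–12),
`intra_rate = 0.3`, `background_rate = 0.25`, and counts from a negative
binomial with mean 100 and dispersion 3. These values were chosen once so
that the count distribution genuinely spans sparse to dense graphs: at
the default threshold about 60–70% of samples survive filtering (so the
filter partitions rather than rubber-stamps), and the class signal is
linearly separable so learning-sanity tests have an unambiguous target.

What the generator deliberately does **not** emulate: positional
structure within chromosomes, correlated aberration clusters beyond the
class signature, per-class intraCA biases (intra events are uniform and
class-free by construction), sample-level label noise, and the long-tail
class imbalance of real catalogues. Passing tests on these cohorts
therefore demonstrate that the pipeline's machinery is correct and that
the model can recover planted chromosome-pair structure — they do not
certify accuracy on real tumor data, where signal is weaker and
confounded.

## Numerical choices and degenerate inputs

* Ties in argmax predictions break towards the lowest class index;
  class order is the sorted label set, recorded in the model.
* Precision/recall with a zero denominator report 0 and set a
  `zero_division` flag; column-normalizing a confusion matrix leaves
  all-zero columns at zero rather than NaN.
* Edgeless graphs are legal everywhere: they featurize to zero matrices,
  have $\bar\kappa = 0$, and still produce a valid class distribution
  (the 24 self-loops added for message passing keep every neighborhood
  non-empty).
* Non-finite training loss aborts with the epoch and batch in the error.
* Reported problem sizes: the learning-sanity suite trains on the
  3×200-sample separable cohort (about 390 graphs after filtering) for
  30–40 epochs, which is well past convergence for this fixture; the
  ablation and determinism suites use 60 and 24 samples per class.
  Everything sits inside the "at most 200 epochs" regime.

## Known limitations

* The GAT is CPU-only and single-threaded; cohorts of tens of thousands
  of graphs would want the hot paths in compiled code.
* No cross-validation harness — a single stratified split with a recorded
  seed, as in the source protocol; trivially addable.
* Whether the original all-pairs computation used ordered pairs on the
  digraph cannot be determined from the text; the unordered-pair
  denominator fixes our convention.
* Model checkpoints are JSON (portable, diffable) and grow with
  parameter count; fine at these scales.
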