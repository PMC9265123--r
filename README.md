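# chromgraph

Cancer-type classification from chromosomal rearrangement endpoints,
represented as per-sample graphs over the 24 human chromosomes.

Structural aberrations (translocations, deletions, inversions,
duplications, insertions) are catalogued as breakpoint pairs — a
"Location From" and a "Location To". `chromgraph` discards all
within-chromosome positional detail and asks what the chromosome-level
wiring alone can say about tumor type. Each tumor sample becomes a
directed multigraph G(V, E) on the fixed node set V = {1, …, 24} (22
autosomes, X = 23, Y = 24): every aberration is an edge from its source
to its sink chromosome, repeated aberrations are parallel edges, and
within-chromosome events are self-loops.

The pipeline has four stages:

1. **Graph construction** from COSMIC-style breakpoint tables (TSV/CSV,
   configurable column mapping), one multigraph per sample.
2. **Informativeness scoring** by average connectivity
   κ̄(G) = Σ_{u<v} κ(u, v) / C(24, 2), where κ(u, v) is the maximum number
   of edge-disjoint u–v paths (Menger), computed as unit-capacity max
   flow with BFS augmenting paths; all pairs at once via a Gomory–Hu
   tree.
3. **Filtering**: samples with κ̄ below a threshold (default 0.3) are too
   sparse to be informative and are removed.
4. **Classification** with a graph attention network: n stacked
   attention layers (default 6, so each chromosome's embedding spans a
   6-hop neighborhood), global max pooling over nodes, a dense
   log-softmax head, multiclass NLL loss, Adam, and class-weighted batch
   sampling to neutralize cohort imbalance.

Flat baselines (feed-forward network, linear/polynomial SVM, kNN over
Euclidean/Minkowski/Mahalanobis distances), evaluation metrics
(confusion matrices, per-class precision/recall/F1, macro and weighted
averages), and a synthetic cohort generator with per-class translocation
signatures make the whole pipeline testable without any database access.

## Worked example

A fully synthetic three-class cohort, filtered, trained and evaluated:

```r
library(chromgraph)

records <- make_separable_cohort(n_per_class = 60, seed = 1)
samples <- group_by_sample(records)
graphs  <- build_cohort_graphs(samples, mode = "integrated")

profiles <- cohort_connectivity(graphs)
parts <- filter_graphs(graphs, profiles, filter_config(tau_low = 0.3))
length(parts$kept)
#> [1] 126

split <- split_dataset(parts$kept, test_fraction = 0.2, seed = 1)
model <- gnn_train(split, gnn_config(max_epochs = 20, seed = 1))
model
#> <chromgraph_model> 6 attention layers, width 64 x 1 head(s), 3 classes
#>   trained 20 epochs; final loss 0.0038, train acc 1.000, test acc 1.000

pred  <- predict(model, split$test)
truth <- vapply(split$test, function(g) g$label, character(1))
classification_report(true_labels = truth, predicted_labels = pred$labels,
                      class_order = model$classes)
#> <eval_report> evaluation unit: graphs
#>       label precision recall f1 support
#>      breast         1      1  1       7
#>  pancreatic         1      1  1      10
#>    prostate         1      1  1       8
#> accuracy: 1.00
#> macro    P/R/F1: 1.00 / 1.00 / 1.00
#> weighted P/R/F1: 1.00 / 1.00 / 1.00
```

Of the 180 generated samples, 126 pass the κ̄ ≥ 0.3 filter (the
generator's count distribution deliberately spans sparse to dense
graphs). The planted class signatures are disjoint chromosome-pair
signatures, so the classifier reaches perfect held-out accuracy within
20 epochs — the point of the fixture is an unambiguous target for the
machinery, not a hard benchmark.

`run_pipeline()` wires the same stages end to end and writes every
artifact (connectivity report, dataset manifest, training log, JSON
model checkpoint, evaluation report, run manifest) into an output
directory; `inst/cli/chromgraph.R` exposes the stages as shell
subcommands (`simulate`, `ingest`, `connectivity`, `filter`, `pipeline`,
`predict`, `baseline`, `sweep-hubs`, …).

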