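#' Filter configuration for connectivity-based graph selection
#'
#' Sparse graphs — too few rearrangement endpoints to form an informative
#' structure — are removed by thresholding the average connectivity of the
#' integrated (inter + intra) graph. `tau_low = 0.3` is the operative
#' default; an optional upper threshold `tau_high` additionally removes very
#' dense graphs, and is off by default.
#'
#' @param tau_low Lower threshold (inclusive: kappa_bar >= tau_low keeps).
#' @param tau_high Optional upper threshold (inclusive), `NULL` to disable.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(tau_low = 0.3, tau_high = NULL) {
  stopifnot(tau_low >= 0)
  if (!is.null(tau_high) && tau_high <= tau_low) {
    stop("tau_high must exceed tau_low")
  }
  structure(list(tau_low = tau_low, tau_high = tau_high,
                 connectivity_basis = "integrated"),
            class = "filter_config")
}

#' Select informative graphs by average connectivity
#'
#' Keeps a graph iff `tau_low <= kappa_bar` and, when `tau_high` is set,
#' `kappa_bar <= tau_high`. Profiles must be computed on the integrated
#' graph regardless of the downstream edge mode: an intra-only graph always
#' has kappa_bar = 0 (self-loops carry no paths between distinct
#' chromosomes), so filtering on the mode-restricted graph would empty the
#' intrachromosomal experiment.
#'
#' @param graphs List of `rearrangement_graph`.
#' @param profiles List of `connectivity_profile`, one per graph, matched by
#'   `sample_id`.
#' @param config A [filter_config()].
#' @return List with `kept` and `dropped` graph lists — an exhaustive,
#'   disjoint partition of the input.
#' @export
filter_graphs <- function(graphs, profiles, config = filter_config()) {
  kb <- vapply(profiles, function(p) p$kappa_bar, numeric(1))
  pid <- vapply(profiles, function(p) p$sample_id, character(1))
  gid <- vapply(graphs, function(g) g$sample_id, character(1))
  miss <- setdiff(gid, pid)
  if (length(miss) > 0) {
    stop("no connectivity profile for sample(s): ",
         paste(miss, collapse = ", "))
  }
  kb <- kb[match(gid, pid)]
  keep <- kb >= config$tau_low
  if (!is.null(config$tau_high)) keep <- keep & kb <= config$tau_high
  list(kept = graphs[keep], dropped = graphs[!keep])
}

#' Class weights inversely proportional to class size
#'
#' The weight of each class is proportional to the reciprocal of its sample
#' count, rescaled so that the weights average 1. Used as per-graph sampling
#' weights so that minority classes are oversampled and batches are drawn
#' with (in expectation) uniform class composition.
#'
#' @param labels Character or factor vector of class labels.
#' @return Named numeric vector of weights, mean 1.
#' @examples
#' class_weights(rep(c("A", "B"), c(30, 10)))  # A 0.5, B 1.5
#' @export
class_weights <- function(labels) {
  if (length(labels) == 0) stop("labels must be non-empty")
  counts <- table(as.character(labels))
  w <- 1 / as.numeric(counts)
  w <- w / mean(w)
  names(w) <- names(counts)
  w
}

#' Stratified train/test split of a graph cohort
#'
#' Splits by sample, stratified by cancer-type label, deterministically for
#' a given seed. Per-class test counts are `round(test_fraction * n_class)`,
#' with at least one test graph per class.
#'
#' @param graphs List of `rearrangement_graph`.
#' @param test_fraction Fraction held out for testing, in (0, 1).
#' @param seed Integer seed controlling the split.
#' @return Object of class `dataset_split`: list with `train`, `test`,
#'   `seed`, `class_weights` (computed on the training labels) and a
#'   `counts` data frame of per-class train/test sizes.
#' @export
split_dataset <- function(graphs, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- vapply(graphs, function(g) g$label, character(1))
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("cannot stratify: class(es) with fewer than 2 graphs: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  test_idx <- integer(0)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (cl in sort(names(tab))) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(test_fraction * length(idx)))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train <- graphs[setdiff(seq_along(graphs), test_idx)]
  test <- graphs[test_idx]
  train_labels <- vapply(train, function(g) g$label, character(1))
  test_labels <- vapply(test, function(g) g$label, character(1))
  counts <- data.frame(
    label = sort(names(tab)),
    n_train = as.integer(table(factor(train_labels, sort(names(tab))))),
    n_test = as.integer(table(factor(test_labels, sort(names(tab))))),
    stringsAsFactors = FALSE
  )
  structure(
    list(train = train, test = test, seed = seed,
         class_weights = class_weights(train_labels), counts = counts),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>", length(x$train), "train /", length(x$test),
      "test graphs (seed", paste0(x$seed, ")\n"))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Draw graph indices with class-balanced weighted sampling
#'
#' Samples indices with replacement, each graph weighted by its class
#' weight, so every class appears in batches with (expected) equal
#' frequency regardless of cohort imbalance.
#'
#' @param labels Label vector, one per graph.
#' @param n Number of draws.
#' @param weights Named class weights; defaults to [class_weights()] of
#'   `labels`.
#' @return Integer vector of length `n`.
#' @export
weighted_sample_indices <- function(labels, n, weights = NULL) {
  labels <- as.character(labels)
  if (is.null(weights)) weights <- class_weights(labels)
  w <- weights[labels]
  sample.int(length(labels), n, replace = TRUE, prob = w)
}

# Seed handling: set the RNG from an integer and restore the caller's state,
# so seeded operations do not perturb the global stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
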