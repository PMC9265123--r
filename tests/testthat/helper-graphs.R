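# shared fixtures: all built in code, no stored data

# minimal record data frame for one sample
make_records <- function(from, to, type = "unknown", sample_id = "S1",
                         label = "breast", pos = NA_real_) {
  n <- length(from)
  data.frame(sample_id = rep_len(sample_id, n),
             cancer_type = rep_len(label, n),
             chrom_from = as.integer(from), chrom_to = as.integer(to),
             pos_from = rep_len(pos, n), pos_to = rep_len(pos, n),
             mutation_type = rep_len(type, n),
             stringsAsFactors = FALSE)
}

# a rearrangement graph straight from edge endpoint vectors
make_graph <- function(from, to, type = "unknown", sample_id = "S1",
                       label = "breast", mode = "integrated") {
  build_graph(sample_id, label,
              make_records(from, to, type, sample_id, label), mode = mode)
}

# random multigraph on <= n_nodes nodes with m edges (self-loops allowed)
random_multigraph <- function(n_nodes, m, allow_loops = FALSE) {
  from <- sample.int(n_nodes, m, replace = TRUE)
  to <- sample.int(n_nodes, m, replace = TRUE)
  if (!allow_loops) {
    loops <- from == to
    to[loops] <- (to[loops] %% n_nodes) + 1L
  }
  make_graph(from, to)
}

# small dense separable cohort for fast learning tests: same class structure
# as make_separable_cohort but fewer samples and aberrations
small_separable_cohort <- function(n_per_class = 40, mean_count = 40,
                                   seed = 2) {
  sig <- function(pairs) {
    data.frame(from = pairs[c(TRUE, FALSE)], to = pairs[c(FALSE, TRUE)],
               prob = rep(0.5, 2))
  }
  cfg <- synthetic_config(
    classes = list(
      synthetic_class("breast", n_per_class, sig(c(1L, 2L, 3L, 4L)),
                      intra_rate = 0.3),
      synthetic_class("pancreatic", n_per_class, sig(c(5L, 6L, 7L, 8L)),
                      intra_rate = 0.3),
      synthetic_class("prostate", n_per_class, sig(c(9L, 10L, 11L, 12L)),
                      intra_rate = 0.3)
    ),
    aberrations_per_sample = list(mean = mean_count, dispersion = 3),
    background_rate = 0.25, seed = seed
  )
  generate_cohort(cfg)
}

# cohort whose class signal lives ONLY in pair co-occurrence: every class
# draws each sample's aberrations from two of four motif pairs, and the
# motif-pair combinations (not the single-pair marginals) define the class.
# Marginally, each class uses each of the four pairs with probability 1/2,
# so a per-aberration classifier carries no signal.
cooccurrence_cohort <- function(n_per_class = 40, m_per_sample = 20,
                                seed = 11) {
  pairs <- list(c(13L, 14L), c(15L, 16L), c(17L, 18L), c(19L, 20L))
  combos <- list(A = list(c(1, 2), c(3, 4)),
                 B = list(c(1, 3), c(2, 4)),
                 C = list(c(1, 4), c(2, 3)))
  set.seed(seed)
  rows <- list()
  for (cls in names(combos)) {
    for (i in seq_len(n_per_class)) {
      combo <- combos[[cls]][[sample(2, 1)]]
      chosen <- pairs[combo]
      pick <- sample(2, m_per_sample, replace = TRUE)
      from <- vapply(pick, function(k) chosen[[k]][1], integer(1))
      to <- vapply(pick, function(k) chosen[[k]][2], integer(1))
      rows[[length(rows) + 1]] <-
        make_records(from, to, sample_id = sprintf("%s_%03d", cls, i),
                     label = cls)
    }
  }
  do.call(rbind, rows)
}

# graphs + split for a record cohort, optionally connectivity-filtered
cohort_split <- function(records, tau = NULL, seed = 0, mode = "integrated") {
  samples <- group_by_sample(records)
  graphs <- build_cohort_graphs(samples, mode = "integrated")
  if (!is.null(tau)) {
    profiles <- cohort_connectivity(graphs)
    graphs <- filter_graphs(graphs, profiles, filter_config(tau))$kept
  }
  if (mode != "integrated") {
    ids <- vapply(graphs, function(g) g$sample_id, character(1))
    graphs <- lapply(ids, function(id) {
      s <- samples[[id]]
      build_graph(s$sample_id, s$cancer_type, s$records, mode = mode)
    })
  }
  split_dataset(graphs, test_fraction = 0.2, seed = seed)
}
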