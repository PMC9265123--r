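# build graphs whose kappa_bar is an exact multiple of 1/276 by wiring a
# clique among the first k active chromosomes
graph_with_kappa_bar <- function(target, sample_id, label = "breast") {
  if (target == 0) return(make_graph(integer(0), integer(0),
                                     sample_id = sample_id, label = label))
  # k parallel 1-2 edges: kappa_bar = k/276
  k <- round(target * 276)
  make_graph(rep(1, k), rep(2, k), sample_id = sample_id, label = label)
}

test_that("threshold filtering keeps exactly the graphs at or above tau", {
  targets <- c(0, 0.1, 0.3, 0.9)
  targets <- round(targets * 276) / 276  # representable kappa_bar values
  graphs <- lapply(seq_along(targets), function(i) {
    graph_with_kappa_bar(targets[i], sprintf("S%d", i))
  })
  profiles <- cohort_connectivity(graphs)
  kb <- vapply(profiles, function(p) p$kappa_bar, numeric(1))
  expect_equal(kb, targets)

  # the threshold is inclusive: a graph sitting exactly at tau_low is kept
  parts <- filter_graphs(graphs, profiles,
                         filter_config(tau_low = targets[3]))
  expect_equal(vapply(parts$kept, function(g) g$sample_id, character(1)),
               c("S3", "S4"))
  expect_equal(vapply(parts$dropped, function(g) g$sample_id, character(1)),
               c("S1", "S2"))
  # exhaustive disjoint partition
  expect_equal(length(parts$kept) + length(parts$dropped), length(graphs))

  # tau_low = 0 keeps everything
  parts0 <- filter_graphs(graphs, profiles, filter_config(tau_low = 0))
  expect_length(parts0$kept, 4)

  # upper threshold removes the densest graph
  parts2 <- filter_graphs(graphs, profiles,
                          filter_config(tau_low = 0.3, tau_high = 0.8))
  expect_equal(vapply(parts2$kept, function(g) g$sample_id, character(1)),
               "S3")
})

test_that("filtering demands a profile for every graph", {
  graphs <- list(make_graph(1, 2, sample_id = "A"),
                 make_graph(3, 4, sample_id = "B"))
  profiles <- cohort_connectivity(graphs[1])
  expect_error(filter_graphs(graphs, profiles, filter_config()), "B")
  expect_error(filter_config(tau_low = 0.3, tau_high = 0.2), "tau_high")
})

test_that("class weights are inverse-frequency, rescaled to mean 1", {
  expect_equal(class_weights(rep(c("A", "B"), c(10, 10))),
               c(A = 1, B = 1))
  expect_equal(class_weights(rep(c("A", "B"), c(30, 10))),
               c(A = 0.5, B = 1.5))
  expect_equal(class_weights(rep("only", 7)), c(only = 1))
  expect_error(class_weights(character(0)), "non-empty")
  w <- class_weights(rep(c("a", "b", "c"), c(50, 30, 20)))
  expect_equal(mean(w), 1)
})

test_that("weighted sampling equalizes class frequencies in expectation", {
  labels <- rep(c("A", "B", "C"), c(300, 80, 20))
  set.seed(42)
  draws <- weighted_sample_indices(labels, 10000)
  counts <- table(labels[draws])
  p <- stats::chisq.test(counts, p = rep(1 / 3, 3))$p.value
  expect_gt(p, 0.01)
})

test_that("stratified splits are deterministic and proportionate", {
  graphs <- c(
    lapply(1:50, function(i) make_graph(1, 2, sample_id = paste0("a", i),
                                        label = "A")),
    lapply(1:30, function(i) make_graph(1, 2, sample_id = paste0("b", i),
                                        label = "B")),
    lapply(1:20, function(i) make_graph(1, 2, sample_id = paste0("c", i),
                                        label = "C"))
  )
  sp <- split_dataset(graphs, test_fraction = 0.2, seed = 7)
  expect_equal(sp$counts$n_test, c(10L, 6L, 4L))
  expect_equal(sp$counts$n_train, c(40L, 24L, 16L))
  # disjoint by sample id
  ids <- function(gl) vapply(gl, function(g) g$sample_id, character(1))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  # identical seeds give identical splits
  sp2 <- split_dataset(graphs, test_fraction = 0.2, seed = 7)
  expect_identical(ids(sp$test), ids(sp2$test))
  sp3 <- split_dataset(graphs, test_fraction = 0.2, seed = 8)
  expect_false(identical(ids(sp3$test), ids(sp$test)))
  # cannot stratify singleton classes
  solo <- c(graphs[1:4], list(make_graph(1, 2, sample_id = "z", label = "Z")))
  expect_error(split_dataset(solo, 0.2, 1), "Z")
})

test_that("an 80/20 split of 452 graphs yields 361 train and 91 test", {
  graphs <- c(
    lapply(1:160, function(i) make_graph(1, 2, sample_id = paste0("a", i),
                                         label = "A")),
    lapply(1:150, function(i) make_graph(1, 2, sample_id = paste0("b", i),
                                         label = "B")),
    lapply(1:142, function(i) make_graph(1, 2, sample_id = paste0("c", i),
                                         label = "C"))
  )
  sp <- split_dataset(graphs, test_fraction = 91 / 452, seed = 1)
  expect_length(sp$train, 361)
  expect_length(sp$test, 91)
})
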