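test_that("aberrations encode as one-hot blocks", {
  rec <- rbind(make_records(2, 3, "unknown"),
               make_records(5, 5, "deletion"))
  f <- featurize_aberrations(rec)
  expect_equal(dim(f$X), c(2, 55))
  expect_equal(which(f$X[1, ] == 1), c(2, 24 + 3, 48 + 7),
               ignore_attr = TRUE)  # src 2, sink 3, type unknown (7th)
  del <- match("deletion", mutation_types())
  expect_equal(which(f$X[2, ] == 1), c(5, 24 + 5, 48 + del),
               ignore_attr = TRUE)
  # exactly one 1 per block per row
  expect_equal(unname(rowSums(f$X[, 1:24])), c(1, 1))
  expect_equal(unname(rowSums(f$X[, 25:48])), c(1, 1))
  expect_equal(unname(rowSums(f$X[, 49:55])), c(1, 1))
  expect_equal(nrow(featurize_aberrations(rec[0, ])$X), 0)
})

test_that("unknown baseline names are rejected with the options listed", {
  rec <- small_separable_cohort(4, mean_count = 10, seed = 23)
  expect_error(run_baseline("boosting", rec), "vanilla_nn")
})

test_that("all baselines beat chance on a separable cohort", {
  rec <- small_separable_cohort(20, mean_count = 15, seed = 29)
  for (nm in c("vanilla_nn", "svm_linear", "svm_poly", "knn")) {
    params <- if (nm == "vanilla_nn") list(epochs = 15) else list()
    rep <- run_baseline(nm, rec, split_seed = 1, params = params)
    expect_gt(rep$accuracy, 1 / 3)
    expect_equal(sum(rep$confusion),
                 sum(rep$per_class$support))
  }
})

test_that("the feed-forward baseline has one output unit per class", {
  rec <- small_separable_cohort(6, mean_count = 10, seed = 31)
  rep <- run_baseline("vanilla_nn", rec, split_seed = 1,
                      params = list(epochs = 2))
  info <- attr(rep, "model_info")
  expect_equal(info$output_units, 3)
  expect_equal(info$hidden, c(60, 60, 60))
})

test_that("1-NN on its own training set is perfect when rows are distinct", {
  # distinct chromosome pairs per aberration so no two rows coincide
  rec <- rbind(
    make_records(c(1, 1, 1, 2), c(2, 3, 4, 3), sample_id = "a", label = "A"),
    make_records(c(5, 5, 5, 6), c(6, 7, 8, 7), sample_id = "b", label = "B"),
    make_records(c(9, 9, 9, 10), c(10, 11, 12, 11), sample_id = "c",
                 label = "C")
  )
  f <- featurize_aberrations(rec)
  pred <- chromgraph:::knn_predict(f$X, f$y, f$X, k = 1)
  expect_equal(mean(pred == f$y), 1)
})

test_that("distance metrics are configurable, including Mahalanobis", {
  rec <- small_separable_cohort(10, mean_count = 12, seed = 41)
  for (metric in c("euclidean", "minkowski", "mahalanobis")) {
    rep <- run_baseline("knn", rec, split_seed = 2,
                        params = list(k = 5, metric = metric))
    expect_gt(rep$accuracy, 1 / 3)
  }
})

test_that("per-sample aggregation is available as an alternative unit", {
  rec <- small_separable_cohort(15, mean_count = 15, seed = 43)
  rep <- run_baseline("knn", rec, split_seed = 3, unit = "sample")
  expect_equal(rep$unit, "samples")
  expect_equal(sum(rep$per_class$support), 9)  # 3 test samples per class
})

test_that("graph classification beats flat baselines on co-occurrence signal", {
  # class identity lives only in which aberration pairs co-occur within a
  # sample; single-aberration marginals are uniform across classes, so
  # per-aberration classifiers cannot rise above chance systematically
  rec <- cooccurrence_cohort(n_per_class = 40, m_per_sample = 16, seed = 47)
  split <- cohort_split(rec, seed = 1)
  model <- gnn_train(split, gnn_config(n_hubs = 2, hidden_dim = 32,
                                       max_epochs = 60, seed = 1))
  gnn_acc <- model$history$test_acc[nrow(model$history)]
  base_accs <- vapply(c("vanilla_nn", "svm_linear", "knn"), function(nm) {
    params <- if (nm == "vanilla_nn") list(epochs = 10) else list(k = 9)
    run_baseline(nm, rec, split_seed = 1, params = params)$accuracy
  }, numeric(1))
  expect_gt(gnn_acc, max(base_accs))
  expect_gt(gnn_acc, 0.6)
  expect_lt(max(base_accs), 0.55)  # flat models hover near chance
})
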