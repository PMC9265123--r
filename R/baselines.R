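#' One-hot feature matrix for individual aberrations
#'
#' Flat per-aberration encoding for the baseline models: one-hot source
#' chromosome (24 columns), one-hot sink chromosome (24) and one-hot
#' mutation type (7), 55 columns in all.
#'
#' @param records Record data frame.
#' @return List with `X` (n x 55 numeric matrix), `y` (character label
#'   vector) and `sample_id` (per-row sample identifiers, used to split by
#'   sample rather than by row).
#' @export
featurize_aberrations <- function(records) {
  n <- nrow(records)
  types <- mutation_types()
  X <- matrix(0, n, 2 * N_CHROM + length(types))
  colnames(X) <- c(paste0("src_", chromosome_token(1:N_CHROM)),
                   paste0("snk_", chromosome_token(1:N_CHROM)),
                   paste0("type_", gsub(" ", "_", types)))
  if (n > 0) {
    X[cbind(1:n, records$chrom_from)] <- 1
    X[cbind(1:n, N_CHROM + records$chrom_to)] <- 1
    X[cbind(1:n, 2 * N_CHROM + match(records$mutation_type, types))] <- 1
  }
  list(X = X, y = records$cancer_type, sample_id = records$sample_id)
}

# ---- small feed-forward network (ReLU, log-softmax, Adam) -------------------

mlp_init <- function(dims) {
  L <- length(dims) - 1
  lapply(seq_len(L), function(l) {
    list(W = glorot(dims[l], dims[l + 1]), b = rep(0, dims[l + 1]))
  })
}

mlp_forward <- function(X, layers) {
  acts <- list(X)
  H <- X
  L <- length(layers)
  for (l in seq_len(L)) {
    H <- H %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(H), length(layers[[l]]$b), byrow = TRUE)
    if (l < L) H <- pmax(H, 0)
    acts[[l + 1]] <- H
  }
  mx <- apply(H, 1, max)
  logp <- H - mx - log(rowSums(exp(H - mx)))
  list(logp = logp, acts = acts)
}

mlp_train <- function(X, y, n_classes, hidden = c(60, 60, 60),
                      epochs = 30L, lr = 0.001, batch_size = 64L,
                      seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  dims <- c(ncol(X), hidden, n_classes)
  layers <- mlp_init(dims)
  L <- length(layers)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      fw <- mlp_forward(X[idx, , drop = FALSE], layers)
      B <- length(idx)
      dlog <- exp(fw$logp)
      dlog[cbind(seq_len(B), y[idx])] <- dlog[cbind(seq_len(B), y[idx])] - 1
      dlog <- dlog / B
      dH <- dlog
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        A <- fw$acts[[l]]
        gW <- crossprod(A, dH)
        gb <- colSums(dH)
        if (l > 1) {
          dH <- dH %*% t(layers[[l]]$W)
          dH <- dH * (fw$acts[[l]] > 0)
        }
        for (pn in c("W", "b")) {
          g <- if (pn == "W") gW else gb
          m[[l]][[pn]] <- b1 * m[[l]][[pn]] + (1 - b1) * g
          v[[l]][[pn]] <- b2 * v[[l]][[pn]] + (1 - b2) * g^2
          mh <- m[[l]][[pn]] / (1 - b1^step)
          vh <- v[[l]][[pn]] / (1 - b2^step)
          layers[[l]][[pn]] <- layers[[l]][[pn]] - lr * mh / (sqrt(vh) + eps)
        }
      }
    }
  }
  layers
}

mlp_predict <- function(X, layers) {
  max.col(mlp_forward(X, layers)$logp, ties.method = "first")
}

# ---- kNN over configurable distances ---------------------------------------

# Mahalanobis distance is realized by whitening with the training-set
# covariance; a ridge term keeps it invertible (one-hot blocks make the raw
# covariance singular).
whiten_transform <- function(Xtr, ridge = 1e-3) {
  S <- stats::cov(Xtr) + diag(ridge, ncol(Xtr))
  backsolve(chol(S), diag(ncol(Xtr)))
}

knn_predict <- function(Xtr, ytr, Xte, k = 5L,
                        metric = c("euclidean", "minkowski", "mahalanobis"),
                        p = 3, classes = sort(unique(ytr)),
                        chunk = 512L) {
  metric <- match.arg(metric)
  if (metric == "mahalanobis") {
    Wh <- whiten_transform(Xtr)
    Xtr <- Xtr %*% Wh
    Xte <- Xte %*% Wh
    metric <- "euclidean"
  }
  k <- min(k, nrow(Xtr))
  pred <- character(nrow(Xte))
  tr_sq <- rowSums(Xtr^2)
  for (start in seq(1, nrow(Xte), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(Xte))
    Xc <- Xte[idx, , drop = FALSE]
    if (metric == "euclidean") {
      D <- outer(rowSums(Xc^2), tr_sq, "+") - 2 * tcrossprod(Xc, Xtr)
      D[D < 0] <- 0
    } else {
      D <- matrix(0, length(idx), nrow(Xtr))
      for (j in seq_len(ncol(Xtr))) {
        D <- D + abs(outer(Xc[, j], Xtr[, j], "-"))^p
      }
    }
    for (i in seq_along(idx)) {
      nn <- order(D[i, ])[seq_len(k)]
      votes <- table(factor(ytr[nn], levels = classes))
      pred[idx[i]] <- classes[which.max(votes)]
    }
  }
  pred
}

# ---- harness ----------------------------------------------------------------

# stratified sample-level split of record rows
split_records_by_sample <- function(features, test_fraction, seed) {
  ids <- unique(features$sample_id)
  lab <- features$y[match(ids, features$sample_id)]
  tab <- table(lab)
  if (any(tab < 2)) {
    stop("cannot stratify: class(es) with fewer than 2 samples")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  test_ids <- character(0)
  for (cl in sort(names(tab))) {
    cl_ids <- ids[lab == cl]
    n_test <- max(1L, round(test_fraction * length(cl_ids)))
    test_ids <- c(test_ids, sample(cl_ids, n_test))
  }
  list(train = !(features$sample_id %in% test_ids),
       test = features$sample_id %in% test_ids)
}

# one feature vector per sample: column sums of its aberration rows
aggregate_by_sample <- function(features) {
  ids <- unique(features$sample_id)
  X <- rowsum(features$X, features$sample_id)
  X <- X[ids, , drop = FALSE]
  list(X = X, y = features$y[match(ids, features$sample_id)],
       sample_id = ids)
}

#' Run one baseline classifier on flat aberration features
#'
#' The comparison harness for the graph model: a feed-forward network
#' (three hidden ReLU layers of 60 units by default), linear or polynomial
#' SVM, or k-nearest neighbours, all on the one-hot per-aberration
#' encoding. Samples (not individual aberrations) are split into train and
#' test so no tumor contributes rows to both sides. By default each
#' aberration is classified on its own; `unit = "sample"` instead
#' aggregates one count vector per sample.
#'
#' @param name One of `"vanilla_nn"`, `"svm_linear"`, `"svm_poly"`,
#'   `"knn"`.
#' @param records Record data frame (or a prebuilt feature list from
#'   [featurize_aberrations()]).
#' @param split_seed Seed for the stratified sample split.
#' @param params Model-specific settings. `vanilla_nn`: `hidden` (default
#'   `c(60, 60, 60)`), `epochs`, `lr`, `batch_size`; `svm_poly`: `degree`;
#'   `knn`: `k`, `metric` (`"euclidean"`, `"minkowski"`,
#'   `"mahalanobis"`), `p`.
#' @param test_fraction Held-out fraction of samples.
#' @param unit `"aberration"` (default) or `"sample"`.
#' @return An `eval_report` on the test rows, with an attribute
#'   `"model_info"` describing the fitted architecture.
#' @export
run_baseline <- function(name, records, split_seed = 1L, params = list(),
                         test_fraction = 0.2,
                         unit = c("aberration", "sample")) {
  unit <- match.arg(unit)
  known <- c("vanilla_nn", "svm_linear", "svm_poly", "knn")
  if (!name %in% known) {
    stop("unknown baseline '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  features <- if (is.data.frame(records)) {
    featurize_aberrations(records)
  } else {
    records
  }
  if (unit == "sample") features <- aggregate_by_sample(features)
  idx <- split_records_by_sample(features, test_fraction, split_seed)
  Xtr <- features$X[idx$train, , drop = FALSE]
  Xte <- features$X[idx$test, , drop = FALSE]
  ytr <- features$y[idx$train]
  yte <- features$y[idx$test]
  classes <- sort(unique(features$y))
  info <- list(name = name, unit = unit)

  if (name == "vanilla_nn") {
    hidden <- params$hidden %||% c(60, 60, 60)
    layers <- mlp_train(Xtr, match(ytr, classes), length(classes),
                        hidden = hidden,
                        epochs = params$epochs %||% 30L,
                        lr = params$lr %||% 0.001,
                        batch_size = params$batch_size %||% 64L,
                        seed = split_seed)
    pred <- classes[mlp_predict(Xte, layers)]
    info$hidden <- hidden
    info$output_units <- length(layers[[length(layers)]]$b)
  } else if (name %in% c("svm_linear", "svm_poly")) {
    kernel <- if (name == "svm_linear") "linear" else "polynomial"
    fit <- e1071::svm(x = Xtr, y = factor(ytr, levels = classes),
                      kernel = kernel,
                      degree = params$degree %||% 3,
                      scale = FALSE)
    pred <- as.character(stats::predict(fit, Xte))
    info$kernel <- kernel
  } else {
    pred <- knn_predict(Xtr, ytr, Xte,
                        k = params$k %||% 5L,
                        metric = params$metric %||% "euclidean",
                        p = params$p %||% 3,
                        classes = classes)
    info$k <- params$k %||% 5L
    info$metric <- params$metric %||% "euclidean"
  }
  report <- classification_report(true_labels = yte, predicted_labels = pred,
                                  class_order = classes,
                                  unit = paste0(unit, "s"))
  attr(report, "model_info") <- info
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
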