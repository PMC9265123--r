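#' Configuration of the graph attention classifier
#'
#' Defaults reproduce the reference training setup: six stacked attention
#' layers (each chromosome's embedding then spans a 6-hop neighborhood),
#' Adam with learning rate 0.001, batch size 10, at most 200 epochs, and
#' dropout 0.2. Hidden width and head count are not dictated by the
#' architecture and are recorded with every trained model.
#'
#' @param n_hubs Number of stacked attention layers (hop radius), 1..10.
#' @param hidden_dim Hidden embedding width per attention head.
#' @param attention_heads Number of attention heads per layer; head outputs
#'   are concatenated.
#' @param dropout Dropout rate applied to node embeddings between layers
#'   during training, in \[0, 1).
#' @param learning_rate Adam learning rate.
#' @param batch_size Graphs per training batch.
#' @param max_epochs Training length; there is no early stopping.
#' @param seed Integer seed governing initialization, sampling and dropout.
#' @param feature_scheme Node feature scheme, see [node_features()].
#' @param dedup_neighborhoods If `TRUE`, parallel edges collapse to a
#'   single entry in each attention neighborhood; by default the
#'   neighborhood is a multiset, so aberration multiplicity shifts
#'   attention mass.
#' @return Object of class `gnn_config`.
#' @export
gnn_config <- function(n_hubs = 6L, hidden_dim = 64L, attention_heads = 1L,
                       dropout = 0.2, learning_rate = 0.001,
                       batch_size = 10L, max_epochs = 200L, seed = 1L,
                       feature_scheme = c("adjacency_row",
                                          "adjacency_row_plus_types"),
                       dedup_neighborhoods = FALSE) {
  feature_scheme <- match.arg(feature_scheme)
  stopifnot(n_hubs >= 1, n_hubs <= 10, hidden_dim >= 1,
            attention_heads >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(n_hubs = as.integer(n_hubs),
                 hidden_dim = as.integer(hidden_dim),
                 attention_heads = as.integer(attention_heads),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 feature_scheme = feature_scheme,
                 dedup_neighborhoods = dedup_neighborhoods),
            class = "gnn_config")
}

# ---- internal numerics ------------------------------------------------------

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# grouped sum of rows of x by integer group g, scattered into n rows
rowsum_full <- function(x, g, n) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  r <- rowsum(x, g)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(r)), ] <- r
  out
}

# grouped max via ordered overwrite: the last write per group is its max
group_max <- function(x, g, n) {
  o <- order(x)
  out <- rep(-Inf, n)
  out[g[o]] <- x[o]
  out
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- parameters -------------------------------------------------------------

init_params <- function(config, input_dim, n_classes) {
  L <- config$n_hubs
  h <- config$hidden_dim
  heads <- config$attention_heads
  layers <- vector("list", L)
  f_in <- input_dim
  for (l in seq_len(L)) {
    layers[[l]] <- lapply(seq_len(heads), function(k) {
      list(W = glorot(f_in, h),
           a_src = stats::runif(h, -sqrt(6 / (h + 1)), sqrt(6 / (h + 1))),
           a_dst = stats::runif(h, -sqrt(6 / (h + 1)), sqrt(6 / (h + 1))))
    })
    f_in <- h * heads
  }
  list(layers = layers,
       W_out = glorot(f_in, n_classes),
       b_out = rep(0, n_classes))
}

# flatten/unflatten for the Adam state
flatten_params <- function(p) {
  out <- list()
  for (l in seq_along(p$layers)) {
    for (k in seq_along(p$layers[[l]])) {
      pre <- sprintf("L%d.H%d.", l, k)
      out[[paste0(pre, "W")]] <- p$layers[[l]][[k]]$W
      out[[paste0(pre, "a_src")]] <- p$layers[[l]][[k]]$a_src
      out[[paste0(pre, "a_dst")]] <- p$layers[[l]][[k]]$a_dst
    }
  }
  out[["W_out"]] <- p$W_out
  out[["b_out"]] <- p$b_out
  out
}

unflatten_params <- function(flat, template) {
  for (l in seq_along(template$layers)) {
    for (k in seq_along(template$layers[[l]])) {
      pre <- sprintf("L%d.H%d.", l, k)
      template$layers[[l]][[k]]$W <- flat[[paste0(pre, "W")]]
      template$layers[[l]][[k]]$a_src <- flat[[paste0(pre, "a_src")]]
      template$layers[[l]][[k]]$a_dst <- flat[[paste0(pre, "a_dst")]]
    }
  }
  template$W_out <- flat[["W_out"]]
  template$b_out <- flat[["b_out"]]
  template
}

# ---- graph preparation ------------------------------------------------------

# Per-graph tensors: feature matrix and message edges (src -> dst), with a
# self-loop added at every node so each chromosome keeps its own state.
prepare_graph <- function(graph, config) {
  X <- node_features(graph, scheme = config$feature_scheme)
  src <- graph$edges$from
  dst <- graph$edges$to
  if (isTRUE(config$dedup_neighborhoods) && length(src) > 0) {
    key <- paste(src, dst)
    keep <- !duplicated(key)
    src <- src[keep]
    dst <- dst[keep]
  }
  list(X = X,
       src = c(src, seq_len(N_CHROM)),
       dst = c(dst, seq_len(N_CHROM)),
       label = graph$label)
}

# Stack several prepared graphs block-diagonally: node rows are offset by
# 24 per graph so one pass of edgewise operations covers the whole batch.
stack_batch <- function(prepared, idx) {
  B <- length(idx)
  offs <- (seq_len(B) - 1L) * N_CHROM
  X <- do.call(rbind, lapply(prepared[idx], function(p) p$X))
  src <- unlist(lapply(seq_len(B),
                       function(i) prepared[[idx[i]]]$src + offs[i]))
  dst <- unlist(lapply(seq_len(B),
                       function(i) prepared[[idx[i]]]$dst + offs[i]))
  list(X = X, src = src, dst = dst, B = B)
}

# ---- forward / backward -----------------------------------------------------

# One attention head on a (possibly stacked) node set.
# Returns activations plus everything the backward pass needs.
gat_head_forward <- function(H, src, dst, par, n) {
  Z <- H %*% par$W
  zs <- as.vector(Z %*% par$a_src)
  zd <- as.vector(Z %*% par$a_dst)
  pre <- zs[src] + zd[dst]
  e <- leaky_relu(pre)
  gm <- group_max(e, dst, n)
  ex <- exp(e - gm[dst])
  denom <- as.vector(rowsum_full(ex, dst, n))
  alpha <- ex / denom[dst]
  M <- rowsum_full(alpha * Z[src, , drop = FALSE], dst, n)
  list(out = elu(M), Z = Z, alpha = alpha, pre = pre, M = M)
}

gat_head_backward <- function(dOut, cache, H, src, dst, par, n) {
  Z <- cache$Z
  alpha <- cache$alpha
  dM <- dOut * ifelse(cache$M > 0, 1, exp(cache$M))
  dMd <- dM[dst, , drop = FALSE]
  Zs <- Z[src, , drop = FALSE]
  dalpha <- rowSums(dMd * Zs)
  dZ <- rowsum_full(alpha * dMd, src, n)
  # softmax over each destination's neighborhood
  Ssum <- as.vector(rowsum_full(alpha * dalpha, dst, n))
  ds <- alpha * (dalpha - Ssum[dst])
  dpre <- ds * ifelse(cache$pre > 0, 1, 0.2)
  dzs <- as.vector(rowsum_full(dpre, src, n))
  dzd <- as.vector(rowsum_full(dpre, dst, n))
  da_src <- as.vector(crossprod(Z, dzs))
  da_dst <- as.vector(crossprod(Z, dzd))
  dZ <- dZ + outer(dzs, par$a_src) + outer(dzd, par$a_dst)
  list(dW = crossprod(H, dZ),
       da_src = da_src, da_dst = da_dst,
       dH = dZ %*% t(par$W))
}

# Full forward over a stacked batch. In training mode dropout masks are
# drawn from the active RNG stream and cached for the backward pass.
gnn_forward_batch <- function(batch, params, config, training = FALSE) {
  n <- nrow(batch$X)
  B <- batch$B
  H <- batch$X
  L <- length(params$layers)
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    heads <- params$layers[[l]]
    hc <- vector("list", length(heads))
    outs <- vector("list", length(heads))
    for (k in seq_along(heads)) {
      hc[[k]] <- gat_head_forward(H, batch$src, batch$dst, heads[[k]], n)
      outs[[k]] <- hc[[k]]$out
    }
    Hnext <- do.call(cbind, outs)
    mask <- NULL
    if (training && config$dropout > 0) {
      mask <- matrix(stats::runif(length(Hnext)) >= config$dropout,
                     nrow(Hnext), ncol(Hnext)) / (1 - config$dropout)
      Hnext <- Hnext * mask
    }
    caches[[l]] <- list(H_in = H, heads = hc, mask = mask)
    H <- Hnext
  }
  # global max pooling per graph, tracking argmax rows for the backward pass
  f <- ncol(H)
  pooled <- matrix(-Inf, B, f)
  amax <- matrix(1L, B, f)
  for (i in seq_len(N_CHROM)) {
    rows <- (seq_len(B) - 1L) * N_CHROM + i
    Hi <- H[rows, , drop = FALSE]
    upd <- Hi > pooled
    pooled[upd] <- Hi[upd]
    amax[upd] <- rep(rows, f)[upd]
  }
  logits <- pooled %*% params$W_out +
    matrix(params$b_out, B, length(params$b_out), byrow = TRUE)
  mx <- apply(logits, 1, max)
  logp <- logits - mx - log(rowSums(exp(logits - mx)))
  list(logp = logp, pooled = pooled, amax = amax, caches = caches, H_top = H)
}

gnn_backward_batch <- function(fw, y, batch, params, config) {
  B <- batch$B
  n <- nrow(batch$X)
  C <- ncol(fw$logp)
  P <- exp(fw$logp)
  dlogits <- P
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits / B
  grads <- list()
  grads[["W_out"]] <- crossprod(fw$pooled, dlogits)
  grads[["b_out"]] <- colSums(dlogits)
  dPooled <- dlogits %*% t(params$W_out)
  f <- ncol(dPooled)
  dH <- matrix(0, n, f)
  idx <- cbind(as.vector(fw$amax), rep(seq_len(f), each = B))
  dH[idx] <- dH[idx] + as.vector(dPooled)
  L <- length(params$layers)
  for (l in rev(seq_len(L))) {
    cache <- caches_l <- fw$caches[[l]]
    if (!is.null(cache$mask)) dH <- dH * cache$mask
    heads <- params$layers[[l]]
    h <- config$hidden_dim
    dH_in <- matrix(0, n, ncol(cache$H_in))
    for (k in seq_along(heads)) {
      cols <- ((k - 1L) * h + 1L):(k * h)
      bk <- gat_head_backward(dH[, cols, drop = FALSE], cache$heads[[k]],
                              cache$H_in, batch$src, batch$dst,
                              heads[[k]], n)
      pre <- sprintf("L%d.H%d.", l, k)
      grads[[paste0(pre, "W")]] <- bk$dW
      grads[[paste0(pre, "a_src")]] <- bk$da_src
      grads[[paste0(pre, "a_dst")]] <- bk$da_dst
      dH_in <- dH_in + bk$dH
    }
    dH <- dH_in
  }
  grads
}

# ---- exposed operations -----------------------------------------------------

#' One round of attention-weighted message aggregation
#'
#' Applies a single graph-attention layer to a 24-row embedding matrix:
#' each chromosome aggregates its in-neighbors' linearly transformed
#' embeddings, weighted by softmax-normalized attention coefficients
#' (scored by a LeakyReLU of learned source/destination projections), then
#' passes the sum through an ELU nonlinearity. Every node must carry at
#' least its self-loop so its neighborhood is non-empty.
#'
#' @param node_embeddings 24 x h numeric matrix.
#' @param edges Data frame or list with integer `src` and `dst` vectors
#'   (directed, message flows src -> dst), self-loops included.
#' @param layer_params List of per-head parameter lists `W`, `a_src`,
#'   `a_dst` (as one slice of a model's `params$layers`).
#' @return List with `output` (24 x h*heads matrix) and `alpha` (list of
#'   per-head attention coefficient vectors aligned with `edges`; each
#'   destination's coefficients are non-negative and sum to 1).
#' @export
gat_aggregate <- function(node_embeddings, edges, layer_params) {
  src <- as.integer(edges$src)
  dst <- as.integer(edges$dst)
  n <- nrow(node_embeddings)
  if (!all(seq_len(n) %in% dst)) {
    stop("every node needs at least a self-loop in the edge list")
  }
  if (!is.null(layer_params$W)) layer_params <- list(layer_params)
  for (p in layer_params) {
    if (nrow(p$W) != ncol(node_embeddings)) {
      stop("shape mismatch: embeddings have ", ncol(node_embeddings),
           " columns but W expects ", nrow(p$W))
    }
  }
  hc <- lapply(layer_params, function(p) {
    gat_head_forward(node_embeddings, src, dst, p, n)
  })
  list(output = do.call(cbind, lapply(hc, function(x) x$out)),
       alpha = lapply(hc, function(x) x$alpha))
}

#' Multiclass negative log likelihood on log-probabilities
#'
#' Mean over the batch of minus the log-probability assigned to the true
#' class, i.e. the negative log likelihood applied to log-softmax outputs.
#'
#' @param predictions Matrix of per-class log-probabilities, one row per
#'   item.
#' @param labels Integer class indices in 1..n_classes.
#' @return Non-negative scalar.
#' @examples
#' nll_loss(log(matrix(1/3, 1, 3)), 2)  # log(3)
#' @export
nll_loss <- function(predictions, labels) {
  if (is.null(dim(predictions))) predictions <- matrix(predictions, 1)
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > ncol(predictions))) {
    stop("label outside 1..", ncol(predictions))
  }
  -mean(predictions[cbind(seq_len(nrow(predictions)), labels)])
}

#' Train the graph attention classifier
#'
#' Trains on the split's training graphs with Adam, drawing each epoch's
#' batches by class-weighted sampling with replacement (so minority
#' classes are oversampled towards uniform batch composition). All
#' stochastic elements — initialization, sampling, dropout — derive from
#' `config$seed`, making runs bitwise reproducible.
#'
#' @param split A `dataset_split` from [split_dataset()].
#' @param config A [gnn_config()].
#' @return Object of class `chromgraph_model`: list with `params`,
#'   `config`, `classes` (label order), `input_dim` and `history` (one row
#'   per epoch: `epoch`, `loss`, `train_acc`, `test_acc`).
#' @export
gnn_train <- function(split, config = gnn_config()) {
  stopifnot(inherits(split, "dataset_split"), length(split$train) > 0)
  classes <- sort(unique(vapply(split$train, function(g) g$label,
                                character(1))))
  y_train <- match(vapply(split$train, function(g) g$label, character(1)),
                   classes)
  y_test <- match(vapply(split$test, function(g) g$label, character(1)),
                  classes)
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  prep_train <- lapply(split$train, prepare_graph, config = config)
  prep_test <- lapply(split$test, prepare_graph, config = config)
  input_dim <- ncol(prep_train[[1]]$X)
  params <- init_params(config, input_dim, length(classes))
  flat <- flatten_params(params)
  m <- lapply(flat, function(x) x * 0)
  v <- lapply(flat, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n_train <- length(prep_train)
  w <- split$class_weights
  labels_chr <- classes[y_train]
  history <- data.frame(epoch = integer(), loss = numeric(),
                        train_acc = numeric(), test_acc = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- weighted_sample_indices(labels_chr, n_train, w)
    n_batches <- ceiling(n_train / config$batch_size)
    epoch_loss <- 0
    for (b in seq_len(n_batches)) {
      lo <- (b - 1L) * config$batch_size + 1L
      hi <- min(b * config$batch_size, n_train)
      idx <- order_idx[lo:hi]
      batch <- stack_batch(prep_train, idx)
      params <- unflatten_params(flat, params)
      fw <- gnn_forward_batch(batch, params, config, training = TRUE)
      loss <- nll_loss(fw$logp, y_train[idx])
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             ", batch ", b)
      }
      epoch_loss <- epoch_loss + loss * length(idx)
      grads <- gnn_backward_batch(fw, y_train[idx], batch, params, config)
      step <- step + 1L
      for (nm in names(flat)) {
        g <- grads[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
        mh <- m[[nm]] / (1 - b1^step)
        vh <- v[[nm]] / (1 - b2^step)
        flat[[nm]] <- flat[[nm]] - config$learning_rate * mh /
          (sqrt(vh) + eps)
      }
    }
    params <- unflatten_params(flat, params)
    train_pred <- predict_prepared(prep_train, params, config)
    test_acc <- if (length(prep_test) > 0) {
      mean(predict_prepared(prep_test, params, config) == y_test)
    } else {
      NA_real_
    }
    history <- rbind(history, data.frame(
      epoch = epoch,
      loss = epoch_loss / (n_batches * config$batch_size),
      train_acc = mean(train_pred == y_train),
      test_acc = test_acc
    ))
  }
  structure(
    list(params = unflatten_params(flat, params), config = config,
         classes = classes, input_dim = input_dim, history = history),
    class = "chromgraph_model"
  )
}

# argmax class indices for a list of prepared graphs (evaluation mode)
predict_prepared <- function(prepared, params, config, chunk = 64L) {
  if (length(prepared) == 0) return(integer(0))
  out <- integer(length(prepared))
  splits <- split(seq_along(prepared),
                  ceiling(seq_along(prepared) / chunk))
  for (s in splits) {
    batch <- stack_batch(prepared, s)
    fw <- gnn_forward_batch(batch, params, config, training = FALSE)
    out[s] <- max.col(fw$logp, ties.method = "first")
  }
  out
}

#' @export
print.chromgraph_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<chromgraph_model>", x$config$n_hubs, "attention layers, width",
      x$config$hidden_dim, "x", x$config$attention_heads, "head(s),",
      length(x$classes), "classes\n")
  cat(sprintf("  trained %d epochs; final loss %.4f, train acc %.3f, test acc %.3f\n",
              nrow(x$history), last$loss, last$train_acc, last$test_acc))
  invisible(x)
}

#' Per-graph class log-probabilities
#'
#' Runs the trained model forward on one graph: stacked attention layers,
#' global max pooling over the 24 chromosome embeddings, dense layer and
#' log-softmax.
#'
#' @param graph A `rearrangement_graph`.
#' @param model A trained `chromgraph_model`.
#' @return Named numeric vector of log-probabilities over the model's
#'   classes (entries <= 0; exponentials sum to 1).
#' @export
gnn_forward <- function(graph, model) {
  stopifnot(inherits(model, "chromgraph_model"))
  prep <- list(prepare_graph(graph, model$config))
  batch <- stack_batch(prep, 1L)
  fw <- gnn_forward_batch(batch, model$params, model$config,
                          training = FALSE)
  stats::setNames(as.vector(fw$logp), model$classes)
}

#' Predict cancer types for a list of graphs
#'
#' @param object A trained `chromgraph_model`.
#' @param graphs List of `rearrangement_graph`.
#' @param ... Unused.
#' @return List with `labels` (character vector; argmax with ties broken
#'   towards the lowest class index) and `prob` (matrix of class
#'   probabilities, rows summing to 1).
#' @export
predict.chromgraph_model <- function(object, graphs, ...) {
  if (length(graphs) == 0) {
    return(list(labels = character(0),
                prob = matrix(numeric(0), 0, length(object$classes),
                              dimnames = list(NULL, object$classes))))
  }
  prepared <- lapply(graphs, prepare_graph, config = object$config)
  logp <- matrix(NA_real_, length(graphs), length(object$classes))
  splits <- split(seq_along(prepared), ceiling(seq_along(prepared) / 64L))
  for (s in splits) {
    batch <- stack_batch(prepared, s)
    fw <- gnn_forward_batch(batch, object$params, object$config,
                            training = FALSE)
    logp[s, ] <- fw$logp
  }
  colnames(logp) <- object$classes
  list(labels = object$classes[max.col(logp, ties.method = "first")],
       prob = exp(logp))
}

#' Accuracy-versus-depth sweep
#'
#' Retrains the model once per requested number of attention layers, with
#' everything else (including the seed) held fixed, and tabulates test
#' accuracy — probing how far across the graph useful aberration context
#' extends.
#'
#' @param split A `dataset_split`.
#' @param config Base [gnn_config()]; `n_hubs` is overridden per run.
#' @param hub_range Integer vector of layer counts to try.
#' @return Data frame with `n_hubs` and `test_accuracy`.
#' @export
hub_sweep <- function(split, config = gnn_config(), hub_range = 1:10) {
  rows <- lapply(hub_range, function(nh) {
    cfg <- config
    cfg$n_hubs <- as.integer(nh)
    model <- gnn_train(split, cfg)
    data.frame(n_hubs = nh,
               test_accuracy = model$history$test_acc[nrow(model$history)])
  })
  do.call(rbind, rows)
}

# ---- checkpoint I/O ---------------------------------------------------------

serialize_array <- function(x) {
  if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
  else list(dim = length(x), data = as.vector(x))
}

deserialize_array <- function(s) {
  d <- unlist(s$dim)
  v <- unlist(s$data)
  if (length(d) == 2) matrix(v, d[1], d[2]) else v
}

#' Save a trained model as a JSON checkpoint
#'
#' The checkpoint carries the full parameter set, the configuration
#' (including the feature scheme) and the class-label ordering, so a
#' reloaded model reproduces predictions exactly.
#'
#' @param model A `chromgraph_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  flat <- flatten_params(model$params)
  doc <- list(
    format = "chromgraph-model",
    version = 1L,
    config = unclass(model$config),
    classes = model$classes,
    input_dim = model$input_dim,
    params = lapply(flat, serialize_array),
    history = model$history
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [write_model()]
#' @param path Checkpoint path.
#' @return A `chromgraph_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "chromgraph-model")) {
    stop("not a chromgraph model checkpoint: ", path)
  }
  cfg <- doc$config
  config <- gnn_config(
    n_hubs = cfg$n_hubs, hidden_dim = cfg$hidden_dim,
    attention_heads = cfg$attention_heads, dropout = cfg$dropout,
    learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs, seed = cfg$seed,
    feature_scheme = cfg$feature_scheme,
    dedup_neighborhoods = isTRUE(cfg$dedup_neighborhoods)
  )
  classes <- unlist(doc$classes)
  template <- init_params_zero(config, doc$input_dim, length(classes))
  flat <- lapply(doc$params, deserialize_array)
  history <- as.data.frame(do.call(rbind, lapply(doc$history, function(r) {
    data.frame(epoch = r$epoch, loss = r$loss, train_acc = r$train_acc,
               test_acc = if (is.null(r$test_acc)) NA_real_ else r$test_acc)
  })))
  structure(
    list(params = unflatten_params(flat, template), config = config,
         classes = classes, input_dim = doc$input_dim, history = history),
    class = "chromgraph_model"
  )
}

init_params_zero <- function(config, input_dim, n_classes) {
  old <- local_seed(0L)
  on.exit(restore_seed(old))
  init_params(config, input_dim, n_classes)
}
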