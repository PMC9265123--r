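#' Symmetrized capacity matrix of a rearrangement graph
#'
#' Each directed aberration edge contributes one unit of undirected
#' capacity between its endpoints; parallel edges add up. Self-loops are
#' dropped: they can never lie on a path between two distinct chromosomes.
#'
#' @param graph A `rearrangement_graph`.
#' @return 24 x 24 symmetric integer matrix of edge multiplicities.
#' @export
capacity_matrix <- function(graph) {
  e <- graph$edges
  e <- e[e$from != e$to, , drop = FALSE]
  if (nrow(e) == 0) return(matrix(0L, N_CHROM, N_CHROM))
  tab <- table(factor(e$from, levels = 1:N_CHROM),
               factor(e$to,   levels = 1:N_CHROM))
  M <- matrix(as.integer(tab), N_CHROM, N_CHROM)
  M + t(M)
}

# Edmonds-Karp: max flow from s to t on a residual capacity matrix.
# BFS shortest augmenting paths; undirected capacity is handled by the
# symmetric initial matrix plus the usual residual updates.
max_flow_matrix <- function(C, s, t) {
  max_flow_residual(C, s, t)$flow
}

max_flow_residual <- function(C, s, t) {
  n <- nrow(C)
  flow <- 0L
  repeat {
    # BFS for an augmenting path
    parent <- rep(NA_integer_, n)
    parent[s] <- s
    queue <- s
    while (length(queue) > 0 && is.na(parent[t])) {
      cur <- queue[1]
      queue <- queue[-1]
      nxt <- which(C[cur, ] > 0 & is.na(parent))
      if (length(nxt) > 0) {
        parent[nxt] <- cur
        queue <- c(queue, nxt)
      }
    }
    if (is.na(parent[t])) break
    # bottleneck along the path
    path <- t
    while (path[1] != s) path <- c(parent[path[1]], path)
    res <- C[cbind(path[-length(path)], path[-1])]
    bn <- min(res)
    C[cbind(path[-length(path)], path[-1])] <-
      C[cbind(path[-length(path)], path[-1])] - bn
    C[cbind(path[-1], path[-length(path)])] <-
      C[cbind(path[-1], path[-length(path)])] + bn
    flow <- flow + bn
  }
  list(flow = flow, residual = C)
}

# nodes reachable from s across positive residual capacity (the s side of a
# minimum cut once no augmenting path remains)
residual_reachable <- function(R, s) {
  n <- nrow(R)
  seen <- rep(FALSE, n)
  seen[s] <- TRUE
  queue <- s
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    nxt <- which(R[cur, ] > 0 & !seen)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  seen
}

# Gusfield's Gomory-Hu construction: n - 1 max-flow calls give a weighted
# tree whose minimum edge weight on the u-v path equals the u-v max flow,
# for every pair at once (valid for undirected/symmetric capacities).
gomory_hu_kappa <- function(C) {
  n <- nrow(C)
  parent <- rep(1L, n)
  fl <- rep(0L, n)
  for (s in 2:n) {
    t <- parent[s]
    res <- max_flow_residual(C, s, t)
    fl[s] <- res$flow
    S <- residual_reachable(res$residual, s)
    side <- which(S & parent == t)
    parent[side[side != s]] <- s
    if (S[parent[t]]) {
      parent[s] <- parent[t]
      parent[t] <- s
      fl[s] <- fl[t]
      fl[t] <- res$flow
    }
  }
  # all-pairs minima over the tree by BFS from each node
  adj <- vector("list", n)
  for (s in 2:n) {
    adj[[s]] <- rbind(adj[[s]], c(parent[s], fl[s]))
    adj[[parent[s]]] <- rbind(adj[[parent[s]]], c(s, fl[s]))
  }
  K <- matrix(0L, n, n)
  for (u in 1:n) {
    minv <- rep(NA_integer_, n)
    minv[u] <- .Machine$integer.max
    queue <- u
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      for (k in seq_len(NROW(adj[[cur]]))) {
        v <- adj[[cur]][k, 1]
        w <- adj[[cur]][k, 2]
        if (is.na(minv[v])) {
          minv[v] <- min(minv[cur], w)
          queue <- c(queue, v)
        }
      }
    }
    minv[u] <- 0L
    K[u, ] <- minv
  }
  K
}

#' Maximum number of edge-disjoint paths between two chromosomes
#'
#' Computes the maximum number of pairwise edge-disjoint paths joining `u`
#' and `v` on the symmetrized multigraph, as unit-capacity maximum flow
#' with breadth-first-search augmenting paths (Edmonds-Karp). By Menger's
#' theorem this equals the minimum number of edges whose removal separates
#' `u` from `v`. Self-loops are ignored. With `node_disjoint = TRUE` the
#' internally node-disjoint variant is computed instead via the standard
#' node-splitting construction.
#'
#' @param graph A `rearrangement_graph`.
#' @param u,v Distinct chromosome indices in 1..24.
#' @param node_disjoint If `TRUE`, count internally node-disjoint paths.
#' @return Non-negative integer.
#' @export
max_edge_disjoint_paths <- function(graph, u, v, node_disjoint = FALSE) {
  stopifnot(u >= 1, u <= N_CHROM, v >= 1, v <= N_CHROM)
  if (u == v) stop("u and v must be distinct chromosomes")
  C <- capacity_matrix(graph)
  if (!node_disjoint) return(max_flow_matrix(C, u, v))
  # node splitting: w_in = w, w_out = w + 24; internal capacity 1 except at
  # the terminals, which are uncapacitated.
  n <- N_CHROM
  big <- sum(C) + 1L
  S <- matrix(0L, 2L * n, 2L * n)
  int_cap <- rep(1L, n)
  int_cap[c(u, v)] <- big
  S[cbind(1:n, 1:n + n)] <- int_cap
  idx <- which(C > 0, arr.ind = TRUE)
  if (nrow(idx) > 0) S[cbind(idx[, 1] + n, idx[, 2])] <- C[idx]
  max_flow_matrix(S, u + n, v)
}

#' Exhaustive oracle for maximum edge-disjoint paths (test-only)
#'
#' Exhaustively searches over simple `u`-`v` paths: recursively picks every
#' possible first path, removes its edges, and recurses, returning the
#' maximal number of edge-disjoint paths found. Exponential by design;
#' refuses graphs with more than 10 edges.
#'
#' @param graph A `rearrangement_graph` with at most 10 edges.
#' @param u,v Distinct chromosome indices.
#' @return Non-negative integer, the true maximum.
#' @export
brute_force_disjoint_paths <- function(graph, u, v) {
  if (u == v) stop("u and v must be distinct chromosomes")
  e <- graph$edges
  e <- e[e$from != e$to, , drop = FALSE]
  if (nrow(e) > 10) {
    stop("oracle refuses graphs with more than 10 edges (got ", nrow(e), ")")
  }
  ea <- e$from
  eb <- e$to

  # all simple u-v paths as sets of edge indices, over available edges
  enumerate_paths <- function(avail) {
    paths <- list()
    walk <- function(node, used_edges, visited) {
      if (node == v) {
        paths[[length(paths) + 1L]] <<- used_edges
        return(invisible(NULL))
      }
      for (i in which(avail)) {
        if (i %in% used_edges) next
        other <- if (ea[i] == node) eb[i] else if (eb[i] == node) ea[i] else NA
        if (is.na(other) || other %in% visited) next
        walk(other, c(used_edges, i), c(visited, other))
      }
    }
    walk(u, integer(0), u)
    paths
  }

  best <- function(avail) {
    paths <- enumerate_paths(avail)
    if (length(paths) == 0) return(0L)
    m <- 0L
    for (p in paths) {
      a2 <- avail
      a2[p] <- FALSE
      m <- max(m, 1L + best(a2))
    }
    m
  }
  best(rep(TRUE, length(ea)))
}

#' Pairwise connectivity matrix of a rearrangement graph
#'
#' kappa(u, v) = maximum number of edge-disjoint u-v paths, for all 276
#' unordered chromosome pairs, mirrored into a symmetric 24 x 24 matrix.
#' The diagonal is not defined for the average and is stored as 0. Isolated
#' chromosomes give zero rows.
#'
#' @param graph A `rearrangement_graph`.
#' @param node_disjoint Passed to [max_edge_disjoint_paths()]; forces the
#'   direct method.
#' @param method `"gomory_hu"` (default) solves all pairs from one
#'   Gomory-Hu tree built with 23 max-flow calls; `"direct"` runs one
#'   max-flow per pair. Both return identical matrices for edge-disjoint
#'   connectivity.
#' @return 24 x 24 symmetric integer matrix.
#' @export
pairwise_connectivity <- function(graph, node_disjoint = FALSE,
                                  method = c("gomory_hu", "direct")) {
  method <- match.arg(method)
  C <- capacity_matrix(graph)
  K <- matrix(0L, N_CHROM, N_CHROM)
  deg <- rowSums(C)
  active <- which(deg > 0)
  if (length(active) < 2) return(K)
  if (!node_disjoint && method == "gomory_hu") {
    return(gomory_hu_kappa(C))
  }
  comp <- components_from_capacity(C)
  for (i in seq_along(active)[-length(active)]) {
    for (j in (i + 1):length(active)) {
      a <- active[i]; b <- active[j]
      if (comp[a] != comp[b]) next
      k <- if (node_disjoint) {
        max_edge_disjoint_paths(graph, a, b, node_disjoint = TRUE)
      } else {
        max_flow_matrix(C, a, b)
      }
      K[a, b] <- K[b, a] <- k
    }
  }
  K
}

# connected components over positive capacities (flow is 0 across components)
components_from_capacity <- function(C) {
  n <- nrow(C)
  comp <- rep(0L, n)
  cid <- 0L
  for (s in 1:n) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      nxt <- which(C[cur, ] > 0 & comp == 0L)
      comp[nxt] <- cid
      queue <- c(queue, nxt)
    }
  }
  comp
}

#' Average graph connectivity
#'
#' The mean over all C(24, 2) = 276 unordered chromosome pairs of the
#' maximum number of edge-disjoint paths joining them — a global measure of
#' how connected a sample's rearrangement structure is. All 276 pairs enter
#' the denominator whether adjacent or not; an edgeless graph scores 0.
#'
#' @param x A `rearrangement_graph`, a `connectivity_profile`, or a
#'   24 x 24 kappa matrix.
#' @return Non-negative scalar.
#' @examples
#' rec <- data.frame(sample_id = "S", cancer_type = "breast",
#'                   chrom_from = 2L, chrom_to = 3L,
#'                   pos_from = NA_real_, pos_to = NA_real_,
#'                   mutation_type = "unknown")
#' g <- build_graph("S", "breast", rec)
#' average_connectivity(g)  # 1/276
#' @export
average_connectivity <- function(x) {
  K <- if (inherits(x, "rearrangement_graph")) {
    pairwise_connectivity(x)
  } else if (inherits(x, "connectivity_profile")) {
    x$kappa
  } else if (is.matrix(x)) {
    x
  } else {
    stop("cannot compute average connectivity for class ",
         paste(class(x), collapse = "/"))
  }
  stopifnot(nrow(K) == N_CHROM, ncol(K) == N_CHROM)
  sum(K[upper.tri(K)]) / choose(N_CHROM, 2)
}

#' Connectivity profile of one graph
#'
#' @param graph A `rearrangement_graph`.
#' @param node_disjoint Passed to [pairwise_connectivity()].
#' @return Object of class `connectivity_profile`: list with `sample_id`,
#'   `kappa` (24 x 24 matrix), `kappa_bar` and `p = 24`.
#' @export
connectivity_profile <- function(graph, node_disjoint = FALSE) {
  K <- pairwise_connectivity(graph, node_disjoint = node_disjoint)
  structure(
    list(sample_id = graph$sample_id, kappa = K,
         kappa_bar = average_connectivity(K), p = N_CHROM),
    class = "connectivity_profile"
  )
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat("<connectivity_profile> sample", x$sample_id,
      sprintf("kappa_bar = %.4f\n", x$kappa_bar))
  invisible(x)
}

#' Connectivity profiles for a cohort
#'
#' @param graphs List of `rearrangement_graph`.
#' @return List of `connectivity_profile`, aligned with `graphs`.
#' @export
cohort_connectivity <- function(graphs) {
  lapply(graphs, connectivity_profile)
}

#' Per-cohort connectivity report
#'
#' @param graphs List of `rearrangement_graph`.
#' @param profiles Matching list of `connectivity_profile` (computed if
#'   missing).
#' @return Data frame `sample_id`, `label`, `n_edges`, `kappa_bar`.
#' @export
connectivity_report <- function(graphs, profiles = NULL) {
  if (is.null(profiles)) profiles <- cohort_connectivity(graphs)
  data.frame(
    sample_id = vapply(graphs, function(g) g$sample_id, character(1)),
    label     = vapply(graphs, function(g) g$label, character(1)),
    n_edges   = vapply(graphs, n_edges, integer(1)),
    kappa_bar = vapply(profiles, function(p) p$kappa_bar, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
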