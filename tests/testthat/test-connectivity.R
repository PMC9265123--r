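test_that("edge-disjoint path counts match hand-derived cases", {
  # two parallel edges give capacity 2
  expect_equal(max_edge_disjoint_paths(make_graph(c(2, 2), c(3, 3)), 2, 3), 2)
  # a single chain has one path through the shared middle node
  expect_equal(max_edge_disjoint_paths(make_graph(c(1, 2), c(2, 3)), 1, 3), 1)
  # triangle: direct edge plus the path through the third node
  tri <- make_graph(c(1, 2, 1), c(2, 3, 3))
  expect_equal(max_edge_disjoint_paths(tri, 1, 3), 2)
  expect_equal(brute_force_disjoint_paths(tri, 1, 3), 2)
  # direction is immaterial under symmetrized capacity
  expect_equal(max_edge_disjoint_paths(tri, 3, 1), 2)
  # self-loops never contribute
  loopy <- make_graph(c(2, 5, 5), c(3, 5, 5))
  expect_equal(max_edge_disjoint_paths(loopy, 2, 3), 1)
  expect_equal(max_edge_disjoint_paths(loopy, 5, 3), 0)
  expect_error(max_edge_disjoint_paths(tri, 2, 2), "distinct")
  expect_error(brute_force_disjoint_paths(tri, 2, 2), "distinct")
})

test_that("oracle refuses oversized graphs", {
  big <- make_graph(rep(1, 11), rep(2, 11))
  expect_error(brute_force_disjoint_paths(big, 1, 2), "10 edges")
  expect_equal(brute_force_disjoint_paths(make_graph(integer(0), integer(0)),
                                          1, 2), 0)
})

test_that("flow solver equals the exhaustive oracle on random multigraphs", {
  set.seed(101)
  for (i in 1:150) {
    n_nodes <- sample(2:5, 1)
    g <- random_multigraph(n_nodes, sample(1:8, 1), allow_loops = TRUE)
    uv <- sample(n_nodes, 2)
    expect_equal(max_edge_disjoint_paths(g, uv[1], uv[2]),
                 brute_force_disjoint_paths(g, uv[1], uv[2]),
                 info = paste("instance", i))
  }
})

test_that("Gomory-Hu and direct per-pair computations agree", {
  set.seed(77)
  for (i in 1:40) {
    g <- random_multigraph(sample(3:8, 1), sample(2:14, 1))
    expect_equal(pairwise_connectivity(g, method = "gomory_hu"),
                 pairwise_connectivity(g, method = "direct"),
                 info = paste("instance", i))
  }
})

test_that("pairwise connectivity matrix has the expected structure", {
  K <- pairwise_connectivity(make_graph(2, 3))
  expect_equal(K[2, 3], 1)
  expect_equal(K[3, 2], 1)
  expect_equal(sum(K), 2)
  expect_equal(pairwise_connectivity(make_graph(integer(0), integer(0))),
               matrix(0L, 24, 24))
  set.seed(5)
  g <- random_multigraph(10, 14)
  K <- pairwise_connectivity(g)
  expect_true(isSymmetric(unname(K + 0)))
  # kappa(u,v) <= min(deg u, deg v), parallel edges counted, loops excluded
  deg <- rowSums(capacity_matrix(g))
  for (u in 1:23) for (v in (u + 1):24) {
    expect_lte(K[u, v], min(deg[u], deg[v]))
  }
})

test_that("average connectivity matches analytic cases", {
  expect_equal(average_connectivity(make_graph(integer(0), integer(0))), 0)
  expect_equal(average_connectivity(make_graph(2, 3)), 1 / 276)
  pairs <- t(utils::combn(24, 2))
  K24 <- make_graph(pairs[, 1], pairs[, 2])
  expect_equal(average_connectivity(K24), 23)
  # kappa_bar = 0 iff all off-diagonal kappa entries are 0
  loops_only <- make_graph(c(4, 9), c(4, 9), "deletion")
  expect_equal(average_connectivity(loops_only), 0)
})

test_that("adding an edge never decreases connectivity", {
  set.seed(202)
  for (i in 1:60) {
    g <- random_multigraph(sample(4:10, 1), sample(1:12, 1))
    K <- pairwise_connectivity(g)
    extra <- sample(24, 2)
    g2 <- make_graph(c(g$edges$from, extra[1]), c(g$edges$to, extra[2]))
    K2 <- pairwise_connectivity(g2)
    expect_true(all(K2 >= K), info = paste("instance", i))
    expect_gte(average_connectivity(K2), average_connectivity(K))
  }
})

test_that("whole-graph connectivity lower-bounds the average on connected graphs", {
  # for a connected graph, min over pairs <= mean over pairs by definition;
  # checked explicitly on random connected instances restricted to their
  # active node set
  set.seed(303)
  for (i in 1:20) {
    n_nodes <- sample(4:7, 1)
    # a random spanning path plus extra edges guarantees connectivity
    perm <- sample(n_nodes)
    from <- perm[-n_nodes]
    to <- perm[-1]
    m_extra <- sample(1:6, 1)
    g <- make_graph(c(from, sample(n_nodes, m_extra, TRUE)),
                    c(to, sample(n_nodes, m_extra, TRUE)))
    g$edges <- g$edges[g$edges$from != g$edges$to, ]
    K <- pairwise_connectivity(g)
    sub <- K[1:n_nodes, 1:n_nodes]
    offdiag <- sub[upper.tri(sub)]
    expect_lte(min(offdiag), mean(offdiag))
    expect_gte(min(offdiag), 1)  # connected
  }
})

test_that("node-disjoint variant is bounded by the edge-disjoint count", {
  # two internally node-disjoint routes but three edge-disjoint ones
  g <- make_graph(c(1, 1, 2, 2, 1, 3), c(2, 2, 3, 3, 4, 4))
  expect_equal(max_edge_disjoint_paths(g, 1, 3), 3)
  expect_equal(max_edge_disjoint_paths(g, 1, 3, node_disjoint = TRUE), 2)
  set.seed(9)
  for (i in 1:25) {
    g <- random_multigraph(sample(3:6, 1), sample(1:8, 1))
    uv <- sample(6, 2)
    expect_lte(max_edge_disjoint_paths(g, uv[1], uv[2], node_disjoint = TRUE),
               max_edge_disjoint_paths(g, uv[1], uv[2]))
  }
})

test_that("connectivity profiles and reports carry kappa_bar per sample", {
  rec <- rbind(make_records(c(1, 2), c(2, 3), sample_id = "S1"),
               make_records(7, 7, "deletion", sample_id = "S2",
                            label = "prostate"))
  graphs <- build_cohort_graphs(group_by_sample(rec))
  profiles <- cohort_connectivity(graphs)
  expect_equal(profiles[[1]]$kappa_bar, 3 / 276)  # pairs 1-2, 2-3, 1-3
  expect_equal(profiles[[2]]$kappa_bar, 0)
  expect_equal(profiles[[1]]$p, 24)
  rep <- connectivity_report(graphs, profiles)
  expect_equal(rep$kappa_bar, c(3 / 276, 0))
  expect_equal(rep$n_edges, c(2L, 1L))
})
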