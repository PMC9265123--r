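N_CHROM <- 24L

#' Build the rearrangement multigraph for one sample
#'
#' Every sample is encoded as a directed multigraph on the fixed node set
#' of 24 chromosomes (22 autosomes, X = 23, Y = 24). Each aberration adds
#' one edge from its source chromosome ("Location From") to its sink
#' chromosome ("Location To"); repeated aberrations give parallel edges and
#' intrachromosomal events give self-loops. Chromosomes without any incident
#' edge remain as isolated nodes, so every graph has exactly 24 nodes.
#'
#' @param sample_id Sample identifier.
#' @param label Cancer-type label of the sample.
#' @param records Record data frame for this sample (all rows must carry
#'   `sample_id`).
#' @param mode Which aberrations to keep: `"integrated"` keeps all,
#'   `"inter"` drops self-loops, `"intra"` keeps only self-loops.
#' @return An object of class `rearrangement_graph`: list with `sample_id`,
#'   `label`, `edges` (data frame `from`, `to`, `mutation_type`), `n_nodes`
#'   and the `mode` it was built under.
#' @examples
#' rec <- data.frame(sample_id = "S1", cancer_type = "breast",
#'                   chrom_from = c(2L, 2L, 5L), chrom_to = c(3L, 3L, 5L),
#'                   pos_from = NA_real_, pos_to = NA_real_,
#'                   mutation_type = c("unknown", "unknown", "deletion"))
#' g <- build_graph("S1", "breast", rec, mode = "integrated")
#' n_edges(g)  # 3
#' @export
build_graph <- function(sample_id, label, records,
                        mode = c("integrated", "inter", "intra")) {
  mode <- match.arg(mode)
  if (nrow(records) > 0 && !all(records$sample_id == sample_id)) {
    stop("records do not all belong to sample '", sample_id, "'")
  }
  keep <- switch(mode,
    integrated = rep(TRUE, nrow(records)),
    inter      = records$chrom_from != records$chrom_to,
    intra      = records$chrom_from == records$chrom_to
  )
  edges <- data.frame(
    from          = as.integer(records$chrom_from[keep]),
    to            = as.integer(records$chrom_to[keep]),
    mutation_type = records$mutation_type[keep],
    stringsAsFactors = FALSE
  )
  structure(
    list(sample_id = sample_id, label = label, edges = edges,
         n_nodes = N_CHROM, mode = mode),
    class = "rearrangement_graph"
  )
}

#' @export
print.rearrangement_graph <- function(x, ...) {
  intra <- sum(x$edges$from == x$edges$to)
  cat("<rearrangement_graph> sample", x$sample_id,
      sprintf("(%s): %d nodes, %d edges (%d inter, %d intra), mode=%s\n",
              x$label, x$n_nodes, nrow(x$edges),
              nrow(x$edges) - intra, intra, x$mode))
  invisible(x)
}

#' Number of edges in a rearrangement graph
#' @param graph A `rearrangement_graph`.
#' @return Integer edge count (parallel edges counted with multiplicity).
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Node attribute matrix for a rearrangement graph
#'
#' Encodes each chromosome's aberrations as a real-valued feature row.
#' `adjacency_row` sets row u to the out-edge counts towards each of the 24
#' chromosomes (d = 24): entry (u, w) is the number of aberrations u -> w,
#' self-loops included on the diagonal. `adjacency_row_plus_types`
#' additionally appends the 7-dimensional count vector of self-loop
#' mutation types at u (d = 31); only intrachromosomal events carry a typed
#' mutation call, so the type block is informative exactly for self-loops.
#'
#' @param graph A `rearrangement_graph`.
#' @param scheme Feature scheme, `"adjacency_row"` (default) or
#'   `"adjacency_row_plus_types"`.
#' @return Numeric matrix with 24 rows and 24 or 31 columns.
#' @export
node_features <- function(graph,
                          scheme = c("adjacency_row",
                                     "adjacency_row_plus_types")) {
  scheme <- match.arg(scheme)
  A <- matrix(0, N_CHROM, N_CHROM)
  e <- graph$edges
  if (nrow(e) > 0) {
    tab <- table(factor(e$from, levels = 1:N_CHROM),
                 factor(e$to,   levels = 1:N_CHROM))
    A <- matrix(as.numeric(tab), N_CHROM, N_CHROM)
  }
  if (scheme == "adjacency_row") return(A)
  Tm <- matrix(0, N_CHROM, length(mutation_types()))
  colnames(Tm) <- mutation_types()
  loops <- e[e$from == e$to, , drop = FALSE]
  if (nrow(loops) > 0) {
    tt <- table(factor(loops$from, levels = 1:N_CHROM),
                factor(loops$mutation_type, levels = mutation_types()))
    Tm <- matrix(as.numeric(tt), N_CHROM, length(mutation_types()))
  }
  cbind(A, Tm)
}

#' Serialize a graph's edge multiset as an adjacency list
#'
#' @param graph A `rearrangement_graph`.
#' @return Data frame with columns `u`, `v`, `mutation_type`, one row per
#'   edge, in insertion order (lossless, order-stable).
#' @export
to_adjacency_list <- function(graph) {
  data.frame(u = graph$edges$from, v = graph$edges$to,
             mutation_type = graph$edges$mutation_type,
             stringsAsFactors = FALSE)
}

#' Rebuild a rearrangement graph from an adjacency list
#'
#' Inverse of [to_adjacency_list()].
#'
#' @param sample_id,label Graph identity.
#' @param adj Data frame with columns `u`, `v`, `mutation_type`.
#' @param mode Mode tag to record on the graph.
#' @return A `rearrangement_graph`.
#' @export
graph_from_adjacency_list <- function(sample_id, label, adj,
                                      mode = "integrated") {
  structure(
    list(sample_id = sample_id, label = label,
         edges = data.frame(from = as.integer(adj$u), to = as.integer(adj$v),
                            mutation_type = as.character(adj$mutation_type),
                            stringsAsFactors = FALSE),
         n_nodes = N_CHROM, mode = mode),
    class = "rearrangement_graph"
  )
}

#' Build one graph per sample for a whole cohort
#'
#' @param sample_table A `sample_table` from [group_by_sample()].
#' @param mode As in [build_graph()].
#' @return List of `rearrangement_graph`, one per sample, in table order.
#' @export
build_cohort_graphs <- function(sample_table, mode = "integrated") {
  lapply(sample_table, function(s) {
    build_graph(s$sample_id, s$cancer_type, s$records, mode = mode)
  })
}

#' Cohort manifest of graph sizes
#'
#' @param graphs List of `rearrangement_graph`.
#' @return Data frame with `sample_id`, `label`, `n_edges`, `n_inter`,
#'   `n_intra`.
#' @export
cohort_manifest <- function(graphs) {
  data.frame(
    sample_id = vapply(graphs, function(g) g$sample_id, character(1)),
    label     = vapply(graphs, function(g) g$label, character(1)),
    n_edges   = vapply(graphs, n_edges, integer(1)),
    n_inter   = vapply(graphs, function(g) sum(g$edges$from != g$edges$to),
                       integer(1)),
    n_intra   = vapply(graphs, function(g) sum(g$edges$from == g$edges$to),
                       integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a graph as a JSON document
#'
#' One document per sample: `{sample_id, label, edges: [[u, v, type], ...]}`.
#'
#' @param graph A `rearrangement_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  edges <- unname(apply(graph$edges, 1, function(r) {
    list(as.integer(r[["from"]]), as.integer(r[["to"]]), r[["mutation_type"]])
  }))
  doc <- list(sample_id = graph$sample_id, label = graph$label,
              edges = if (nrow(graph$edges) == 0) list() else edges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a graph from its JSON document
#' @param path Path written by [write_graph_json()].
#' @return A `rearrangement_graph`.
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (length(doc$edges) == 0) {
    adj <- data.frame(u = integer(), v = integer(),
                      mutation_type = character())
  } else {
    adj <- data.frame(
      u = vapply(doc$edges, function(e) as.integer(e[[1]]), integer(1)),
      v = vapply(doc$edges, function(e) as.integer(e[[2]]), integer(1)),
      mutation_type = vapply(doc$edges, function(e) as.character(e[[3]]),
                             character(1)),
      stringsAsFactors = FALSE
    )
  }
  graph_from_adjacency_list(doc$sample_id, doc$label, adj)
}
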