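#' Generate a scale-free (preferential attachment) network
#'
#' Grows a connected undirected graph from a two-node seed; every subsequent
#' node attaches `m` edges to existing nodes with probability proportional to
#' degree raised to `power`. With this growth convention the edge count obeys
#' the closed form `|E| = 1 + m * (n - 2)` (the second node can only attach a
#' single edge).
#'
#' @param n number of nodes (>= 2).
#' @param m edges attached by each new node (>= 1, < n).
#' @param power preferential attachment exponent.
#' @param seed optional integer; when given, the graph is generated under this
#'   seed without disturbing the caller's RNG stream.
#' @return an undirected simple connected [igraph][igraph::igraph-package]
#'   graph with nodes indexed `1..n`.
#' @examples
#' g <- generate_ba_graph(400, m = 2, power = 1.3, seed = 1)
#' igraph::ecount(g)  # 797
#' @export
generate_ba_graph <- function(n, m, power = 1, seed = NULL) {
  if (n < 2) stop("`n` must be at least 2")
  if (m < 1 || m >= n) stop("`m` must satisfy 1 <= m < n")
  with_seed(seed, {
    g <- igraph::sample_pa(n, power = power, m = m, directed = FALSE)
    check_graph(g)
  })
}

#' Generate a small-world (rewired ring lattice) network
#'
#' Ring lattice on `n` nodes where every node is connected to its `nei`
#' nearest neighbours on each side (lattice degree `2 * nei`); each edge is
#' then rewired with probability `p`, avoiding self-loops and duplicate edges,
#' so the edge count stays exactly `n * nei`.
#'
#' @param n number of nodes (must exceed `2 * nei`).
#' @param nei per-side neighbourhood size.
#' @param p rewiring probability in `[0, 1]`.
#' @inheritParams generate_ba_graph
#' @return an undirected simple igraph graph.
#' @examples
#' g <- generate_ws_graph(400, nei = 2, p = 0.1, seed = 1)
#' igraph::ecount(g)  # 800
#' @export
generate_ws_graph <- function(n, nei, p, seed = NULL) {
  if (p < 0 || p > 1) stop("`p` must be a probability in [0, 1]")
  if (n <= 2 * nei) stop("`n` must exceed 2 * nei")
  with_seed(seed, {
    g <- igraph::sample_smallworld(1, n, nei, p, loops = FALSE, multiple = FALSE)
    check_graph(g)
  })
}

#' Read a graph from a whitespace-separated edge list
#'
#' Each non-comment line holds two node labels. Arbitrary labels are remapped
#' to integer ids `1..|V|` in order of first appearance; duplicate edges are
#' collapsed. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return an undirected simple igraph graph; the original labels are kept in
#'   the `name` vertex attribute.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0)
    stop(sprintf("malformed edge list line %d: '%s'", lineno[bad[1]], lines[bad[1]]))
  from <- vapply(parts, `[`, "", 1L)
  to <- vapply(parts, `[`, "", 2L)
  loops <- which(from == to)
  if (length(loops) > 0)
    stop(sprintf("self-loop on line %d: '%s'", lineno[loops[1]], lines[loops[1]]))
  labels <- unique(c(rbind(from, to)))  # first-appearance order, row-wise
  g <- igraph::graph_from_edgelist(
    cbind(match(from, labels), match(to, labels)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(labels) - igraph::vcount(g)))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::V(g)$name <- labels
  g
}

#' Write a graph as a whitespace-separated edge list
#'
#' @param graph an igraph graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  check_graph(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Largest connected component
#'
#' Induced subgraph on the largest component, reindexed `1..n'`. Ties between
#' equally sized components are broken in favour of the component containing
#' the smallest original node index.
#'
#' @param graph an igraph graph.
#' @return an igraph graph.
#' @export
largest_component <- function(graph) {
  check_graph(graph)
  if (igraph::vcount(graph) == 0) stop("empty graph")
  comp <- igraph::components(graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    first_member <- vapply(best, function(k) min(which(comp$membership == k)), 1L)
    best <- best[which.min(first_member)]
  }
  igraph::induced_subgraph(graph, which(comp$membership == best))
}

#' Topological summary of a network
#'
#' Average degree `<k> = 2|E|/|V|`, degree assortativity, degree heterogeneity
#' `H = <k^2>/<k>^2` (1 iff the graph is regular), and average path length in
#' unweighted edge hops over all ordered reachable pairs (computed on the
#' largest component when the graph is disconnected).
#'
#' @param graph an igraph graph with at least 2 nodes.
#' @return a list with elements `node_count`, `edge_count`, `avg_degree`,
#'   `assortativity`, `heterogeneity`, `avg_path_length`.
#' @examples
#' topology_summary(generate_ws_graph(400, 2, 0.1, seed = 1))$avg_degree  # 4
#' @export
topology_summary <- function(graph) {
  check_graph(graph)
  n <- igraph::vcount(graph)
  if (n < 2) stop("graph must have at least 2 nodes")
  deg <- igraph::degree(graph)
  k1 <- mean(deg)
  apl_graph <- if (igraph::is_connected(graph)) graph else largest_component(graph)
  structure(list(
    node_count = n,
    edge_count = igraph::ecount(graph),
    avg_degree = k1,
    assortativity = igraph::assortativity_degree(graph),
    heterogeneity = mean(deg^2) / k1^2,
    avg_path_length = igraph::mean_distance(apl_graph, directed = FALSE)
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(
    "Network: |V| = %d, |E| = %d\n  <k> = %.3f  assortativity = %.3f  H = %.3f  APL = %.3f\n",
    x$node_count, x$edge_count, x$avg_degree, x$assortativity,
    x$heterogeneity, x$avg_path_length))
  invisible(x)
}
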