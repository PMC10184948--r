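#' Default number of retained sequences per observation area
#'
#' `eta = 2 * ceiling(<k>)` where `<k>` is the average degree, e.g. 8 on a
#' degree-4 network and 20 when `<k> = 9.62`.
#'
#' @param graph an igraph graph.
#' @return an integer.
#' @export
default_eta <- function(graph) {
  check_graph(graph)
  as.integer(2 * ceiling(mean(igraph::degree(graph))))
}

#' Trace a single sequence feature from an observer
#'
#' Walks the infector chain backwards from `observer` while the current node
#' stays inside `area` and is informed, then reverses the walk so the
#' earliest-informed node comes first. Chains longer than `l_max` are
#' truncated by dropping the latest-informed nodes; chains shorter than 2
#' nodes carry no direction information and yield `NULL`.
#'
#' @param snapshot a [diffusion_snapshot][simulate_diffusion()].
#' @param area integer vector of area member ids.
#' @param observer a node id inside `area`.
#' @param l_max maximum sequence length.
#' @return an integer vector of 2..`l_max` node ids, or `NULL`.
#' @export
trace_sequence <- function(snapshot, area, observer, l_max = 4) {
  stopifnot(inherits(snapshot, "diffusion_snapshot"))
  if (!observer %in% area) stop("`observer` must belong to `area`")
  seq <- cpp_trace_sequence(snapshot$time, snapshot$infector,
                            as.integer(area), as.integer(observer),
                            as.integer(l_max))
  if (length(seq) == 0) NULL else seq
}

#' Build the snapshot feature from observer diffusion characteristics
#'
#' Observation areas are first ordered by the mean informed time of their
#' informed observers (earliest first; areas with no informed observer come
#' last, keeping their original relative order), so the group closest to the
#' source occupies a stable slot. Then, per area, the infector chain of every
#' observer is traced ([trace_sequence()]), duplicates are removed, sequences
#' are ordered longest first (ties by lexicographic node order) and only the
#' first `eta` are kept.
#'
#' @param snapshot a `diffusion_snapshot`.
#' @param areas an [observation_areas][build_observation_areas()] object built
#'   on the same graph.
#' @param l_max maximum sequence length (default 4).
#' @param eta maximum number of sequences kept per group; use
#'   [default_eta()] for the `2 * ceiling(<k>)` rule.
#' @param keep_shortest when a group exceeds `eta` sequences, drop the longest
#'   instead of the shortest; the default keeps the longest chains.
#' @return an object of class `snapshot_feature`: list with `groups` (K lists
#'   of integer sequences, in sorted-area order), `area_order` (original area
#'   index of each group), `l_max`, `eta`, `n_nodes`.
#' @examples
#' g <- generate_ba_graph(100, 2, 1.3, seed = 1)
#' a <- build_observation_areas(g, select_vital_nodes(g, 0.02), h = 1)
#' set.seed(1)
#' s <- simulate_diffusion(g, source = 10, beta = 0.7)
#' f <- build_snapshot_feature(s, a, l_max = 4, eta = default_eta(g))
#' lengths(f$groups)
#' @export
build_snapshot_feature <- function(snapshot, areas, l_max = 4, eta = 8L,
                                   keep_shortest = FALSE) {
  stopifnot(inherits(snapshot, "diffusion_snapshot"),
            inherits(areas, "observation_areas"))
  if (snapshot$n_nodes != areas$n_nodes)
    stop("snapshot and observation areas were built on different graphs")
  if (l_max < 2) stop("`l_max` must be at least 2")
  if (eta < 1) stop("`eta` must be at least 1")
  res <- cpp_build_feature(snapshot$time, snapshot$infector, areas$areas,
                           as.integer(l_max), as.integer(eta), keep_shortest)
  structure(list(groups = res$groups, area_order = res$area_order,
                 l_max = as.integer(l_max), eta = as.integer(eta),
                 n_nodes = snapshot$n_nodes),
            class = "snapshot_feature")
}

#' @export
print.snapshot_feature <- function(x, ...) {
  cat(sprintf("Snapshot feature: K = %d groups (l_max = %d, eta = %d); %s sequences\n",
              length(x$groups), x$l_max, x$eta,
              paste(lengths(x$groups), collapse = "/")))
  invisible(x)
}

#' Write a snapshot feature as plain text
#'
#' Per group a header `# area i vital=v` followed by one line of
#' space-separated node ids per sequence.
#'
#' @param feature a `snapshot_feature`.
#' @param areas the `observation_areas` the feature was built from (for the
#'   vital-node annotation); optional.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_snapshot_feature <- function(feature, path, areas = NULL) {
  stopifnot(inherits(feature, "snapshot_feature"))
  out <- character(0)
  for (g in seq_along(feature$groups)) {
    orig <- feature$area_order[g]
    vital <- if (!is.null(areas)) areas$vital_nodes[orig] else NA
    out <- c(out, sprintf("# area %d vital=%s", orig, vital),
             vapply(feature$groups[[g]], paste, "", collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}
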