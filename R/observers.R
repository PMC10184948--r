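#' Select vital nodes by degree centrality
#'
#' Picks the `K = ceiling(fraction * |V|)` nodes of highest degree; ties at
#' the cut are broken in favour of the smallest node id so the selection is
#' deterministic. A different centrality can be plugged in through `ranking`.
#'
#' @param graph an igraph graph.
#' @param fraction proportion of nodes to select, in `(0, 1]`. The default 1%
#'   gives e.g. K = 4 on a 400-node network and K = 40 on a 3982-node one.
#' @param ranking optional function `graph -> numeric` returning a score per
#'   node (higher = more vital); defaults to degree centrality.
#' @return integer vector of `K` node ids.
#' @export
select_vital_nodes <- function(graph, fraction = 0.01, ranking = NULL) {
  check_graph(graph)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  n <- igraph::vcount(graph)
  K <- as.integer(ceiling(fraction * n))
  score <- if (is.null(ranking)) igraph::degree(graph) else ranking(graph)
  if (length(score) != n) stop("ranking must return one score per node")
  ord <- order(-score, seq_len(n))
  sort(ord[seq_len(K)])
}

#' Build observation areas around vital nodes
#'
#' Every observation area is the closed `h`-hop ball around one vital node;
#' areas may overlap, and the observer set is their union.
#'
#' @param graph an igraph graph.
#' @param vital_nodes integer vector of area centres.
#' @param h hop radius (>= 0); `h = 0` gives singleton areas.
#' @return an object of class `observation_areas`: list with `areas` (list of
#'   sorted node-id vectors), `vital_nodes`, `h`, `observers` (sorted union)
#'   and `n_nodes`.
#' @examples
#' g <- generate_ba_graph(100, 2, 1.3, seed = 1)
#' a <- build_observation_areas(g, select_vital_nodes(g), h = 1)
#' length(a$observers)
#' @export
build_observation_areas <- function(graph, vital_nodes, h = 1) {
  check_graph(graph)
  n <- igraph::vcount(graph)
  vital_nodes <- as.integer(vital_nodes)
  if (any(is.na(vital_nodes)) || any(vital_nodes < 1) || any(vital_nodes > n))
    stop("vital nodes must be node ids in 1..|V|")
  if (h < 0) stop("`h` must be non-negative")
  balls <- igraph::ego(graph, order = h, nodes = vital_nodes, mode = "all")
  areas <- lapply(balls, function(b) sort(as.integer(b)))
  structure(list(areas = areas, vital_nodes = vital_nodes, h = as.integer(h),
                 observers = sort(unique(unlist(areas))), n_nodes = as.integer(n)),
            class = "observation_areas")
}

#' @export
print.observation_areas <- function(x, ...) {
  cat(sprintf("Observation areas: K = %d, h = %d, |O| = %d of %d nodes\n",
              length(x$areas), x$h, length(x$observers), x$n_nodes))
  invisible(x)
}

#' Write / read observation areas
#'
#' One line per area: `vital_id: member ids...`; a header comment carries the
#' hop radius and node count.
#'
#' @param areas an `observation_areas` object.
#' @param path file path.
#' @return `path` (write) or the reconstructed object (read).
#' @export
write_area_set <- function(areas, path) {
  stopifnot(inherits(areas, "observation_areas"))
  hdr <- sprintf("# h=%d n=%d", areas$h, areas$n_nodes)
  rows <- mapply(function(v, a) paste0(v, ": ", paste(a, collapse = " ")),
                 areas$vital_nodes, areas$areas)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_area_set
#' @export
read_area_set <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  get_num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[0-9]+"), hdr))
    as.integer(sub(paste0(key, "="), "", m))
  }
  parts <- strsplit(lines[-1], ":", fixed = TRUE)
  vital <- vapply(parts, function(p) as.integer(trimws(p[1])), 1L)
  areas <- lapply(parts, function(p)
    sort(as.integer(strsplit(trimws(p[2]), "\\s+")[[1]])))
  structure(list(areas = areas, vital_nodes = vital, h = get_num("h"),
                 observers = sort(unique(unlist(areas))), n_nodes = get_num("n")),
            class = "observation_areas")
}
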