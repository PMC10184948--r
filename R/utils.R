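# internal helpers

# run `code` under a temporary seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sorted integer adjacency list (1-based) from an igraph object
graph_adjacency <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  al <- igraph::as_adj_list(graph, mode = "all")
  lapply(al, function(v) sort(as.integer(v)))
}

check_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("`graph` must be an igraph object")
  if (igraph::is_directed(graph)) stop("`graph` must be undirected")
  if (!igraph::is_simple(graph)) stop("`graph` must be simple (no loops or multi-edges)")
  invisible(graph)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
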