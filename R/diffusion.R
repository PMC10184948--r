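#' Gaussian propagation delay model
#'
#' Per-contact propagation delays are independent draws from `N(mu, sigma^2)`
#' truncated to positive values by resampling. The default `mu = 4`,
#' `sigma = 1` keeps the ratio `mu/sigma = 4`, where the truncation removes
#' less than `1e-4` of the mass.
#'
#' @param mu mean delay (> 0).
#' @param sigma delay standard deviation (> 0).
#' @return an object of class `delay_model`.
#' @export
delay_model <- function(mu = 4, sigma = 1) {
  if (!is.numeric(mu) || mu <= 0) stop("`mu` must be positive")
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be positive")
  structure(list(mu = mu, sigma = sigma), class = "delay_model")
}

#' @export
print.delay_model <- function(x, ...) {
  cat(sprintf("Gaussian delay model: mu = %g, sigma = %g (mu/sigma = %g)\n",
              x$mu, x$sigma, x$mu / x$sigma))
  invisible(x)
}

#' Sample propagation delays
#'
#' @param delay a [delay_model()].
#' @param n number of draws.
#' @return a numeric vector of `n` positive delays.
#' @export
sample_delay <- function(delay = delay_model(), n = 1) {
  stopifnot(inherits(delay, "delay_model"))
  out <- rnorm(n, delay$mu, delay$sigma)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), delay$mu, delay$sigma)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Draw the fixed per-edge propagation delays of a network
#'
#' The propagation delay can be treated as a property of each link, drawn once
#' per network from the delay model and shared by every diffusion run on it
#' (as for physical link latencies). Under fixed delays, repeated cascades
#' from the same source are strongly correlated -- identical when `beta = 1`
#' -- which is what makes classifier-based source identification learnable.
#'
#' @param graph an igraph graph.
#' @param delay a [delay_model()].
#' @param seed optional seed used locally.
#' @return numeric vector of positive delays aligned with the graph's edges.
#' @export
sample_edge_delays <- function(graph, delay = delay_model(), seed = NULL) {
  check_graph(graph)
  with_seed(seed, sample_delay(delay, igraph::ecount(graph)))
}

# per-edge delays rearranged to match graph_adjacency(): one numeric vector
# per vertex, aligned with its sorted neighbour list
edge_delay_adjacency <- function(graph, edge_delays) {
  if (length(edge_delays) != igraph::ecount(graph))
    stop("`edge_delays` must hold one delay per edge")
  adj <- graph_adjacency(graph)
  lapply(seq_along(adj), function(v) {
    if (length(adj[[v]]) == 0) return(numeric(0))
    eids <- igraph::get_edge_ids(graph, rbind(v, adj[[v]]))
    edge_delays[eids]
  })
}

#' Simulate a diffusion process and record its snapshot
#'
#' Event-driven continuous-time spreading: the source is informed at time 0;
#' when a node `v` becomes informed it attempts to transmit to every neighbour
#' except its own infector, each attempt succeeding independently with
#' probability `beta` and arriving after a fresh positive Gaussian delay. By
#' default a failed attempt towards a neighbour is retried after a further
#' delay until it succeeds, so the effective per-contact delay is a
#' Geometric(`beta`)-stopped sum of delay draws, the transmission probability
#' shapes the timing of the cascade, and the process terminates only once no
#' reachable node is ignorant (`beta = 0` transmits nothing). With
#' `single_attempt = TRUE` every directed contact gets exactly one Bernoulli
#' attempt and cascades can die out early, leaving partially informed
#' snapshots. In both modes a node is informed by exactly the earliest
#' successful arrival (ties broken by smallest sender id).
#'
#' @param graph an undirected simple igraph graph.
#' @param source source node id (1-based).
#' @param beta per-contact transmission probability in `[0, 1]`.
#' @param delay a [delay_model()].
#' @param single_attempt `TRUE` for one transmission attempt per directed
#'   contact instead of retry-until-success.
#' @param edge_delays optional fixed per-edge delays from
#'   [sample_edge_delays()]; when given, every attempt over an edge takes that
#'   edge's delay (retries repeat it) instead of a fresh draw.
#' @param record_contacts when `TRUE`, every successful contact `(from, to)`
#'   and its realised (effective) delay is returned, which lets a weighted
#'   shortest-path computation replay the identical realisation.
#' @return an object of class `diffusion_snapshot`: list with `source`,
#'   `beta`, `time` (numeric per node, `NA` = ignorant), `infector` (integer
#'   per node, `NA` for the source and ignorant nodes), `n_nodes`, `mu`,
#'   `sigma`, and optionally `contacts` (matrix `from, to, delay`).
#' @examples
#' g <- generate_ba_graph(50, 2, 1.3, seed = 1)
#' set.seed(7)
#' s <- simulate_diffusion(g, source = 3, beta = 0.5)
#' sum(!is.na(s$time))  # informed nodes
#' @export
simulate_diffusion <- function(graph, source, beta, delay = delay_model(),
                               edge_delays = NULL, single_attempt = FALSE,
                               record_contacts = FALSE) {
  check_graph(graph)
  n <- igraph::vcount(graph)
  if (length(source) != 1 || is.na(source) || source < 1 || source > n)
    stop("`source` must be a node id in 1..|V|")
  if (beta < 0 || beta > 1) stop("`beta` must be in [0, 1]")
  stopifnot(inherits(delay, "delay_model"))
  ed <- if (is.null(edge_delays)) NULL else edge_delay_adjacency(graph, edge_delays)
  res <- cpp_simulate(graph_adjacency(graph), as.integer(source), beta,
                      delay$mu, delay$sigma, single_attempt, ed,
                      record_contacts)
  out <- list(source = as.integer(source), beta = beta, time = res$time,
              infector = res$infector, n_nodes = as.integer(n),
              mu = delay$mu, sigma = delay$sigma)
  if (record_contacts) out$contacts <- res$contacts
  structure(out, class = "diffusion_snapshot")
}

#' @export
print.diffusion_snapshot <- function(x, ...) {
  cat(sprintf(
    "Diffusion snapshot: source = %d, beta = %g, informed %d / %d nodes\n",
    x$source, x$beta, sum(!is.na(x$time)), x$n_nodes))
  invisible(x)
}

#' Write / read a diffusion snapshot
#'
#' Tab-separated rows `node  informed_time  infector` with `-` for ignorant or
#' absent entries, preceded by a header comment carrying the simulation
#' parameters.
#'
#' @param snapshot a `diffusion_snapshot`.
#' @param path file path.
#' @return `path` (write) or the reconstructed `diffusion_snapshot` (read).
#' @export
write_snapshot <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "diffusion_snapshot"))
  hdr <- sprintf("# source=%d beta=%g mu=%g sigma=%g n=%d",
                 snapshot$source, snapshot$beta, snapshot$mu, snapshot$sigma,
                 snapshot$n_nodes)
  fmt <- function(v) ifelse(is.na(v), "-", as.character(v))
  rows <- paste(seq_len(snapshot$n_nodes), fmt(snapshot$time),
                fmt(snapshot$infector), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  get_num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.eE+]+"), hdr))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  n <- length(body)
  time <- rep(NA_real_, n)
  infector <- rep(NA_integer_, n)
  for (row in body) {
    i <- as.integer(row[1])
    if (row[2] != "-") time[i] <- as.numeric(row[2])
    if (row[3] != "-") infector[i] <- as.integer(row[3])
  }
  structure(list(source = as.integer(get_num("source")), beta = get_num("beta"),
                 time = time, infector = infector, n_nodes = as.integer(get_num("n")),
                 mu = get_num("mu"), sigma = get_num("sigma")),
            class = "diffusion_snapshot")
}
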