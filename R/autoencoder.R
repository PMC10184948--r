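#' Configuration of the sequence autoencoder
#'
#' The encoder consumes `|V|`-dimensional one-hot node vectors and emits a
#' `code_dim`-dimensional hidden state per step; the decoder reconstructs the
#' one-hot input from the codes. The default code dimension follows the
#' network size: 8 below 1000 nodes, 16 from 1000 nodes on.
#'
#' @param n_nodes vocabulary size `|V|`.
#' @param code_dim code dimension; default by the size rule above.
#' @param l_max maximum sequence length (default 4).
#' @param l_range lengths of training sequences (node counts, default 2:4).
#' @param batch_size,learning_rate,epochs training hyper-parameters (Adam).
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(n_nodes, code_dim = NULL, l_max = 4L, l_range = 2:4,
                           batch_size = 256L, learning_rate = 0.01,
                           epochs = 40L) {
  if (n_nodes < 2) stop("`n_nodes` must be at least 2")
  code_dim <- code_dim %||% (if (n_nodes < 1000) 8L else 16L)
  if (min(l_range) < 2 || max(l_range) > l_max)
    stop("`l_range` must lie within [2, l_max]")
  structure(list(n_nodes = as.integer(n_nodes), code_dim = as.integer(code_dim),
                 l_max = as.integer(l_max), l_range = as.integer(l_range),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs)),
            class = "encoder_config")
}

#' Enumerate or sample training sequences from a graph
#'
#' Directed simple paths whose node counts fall in `l_range`. When the total
#' number of such paths does not exceed `cap` they are enumerated
#' exhaustively; otherwise distinct paths are collected by uniform random
#' walks without immediate backtracking until `cap` is reached.
#'
#' @param graph an igraph graph.
#' @param l_range node counts of the paths (default 2:4).
#' @param cap maximum corpus size (default unlimited = exhaustive).
#' @param seed optional RNG seed for the sampling branch.
#' @return a list with `idx` (matrix of node ids, `NA`-padded) and `lens`.
#' @examples
#' enumerate_training_sequences(generate_ba_graph(10, 1, seed = 1))$lens
#' @export
enumerate_training_sequences <- function(graph, l_range = 2:4, cap = Inf,
                                         seed = NULL) {
  check_graph(graph)
  if (igraph::vcount(graph) == 0) stop("empty graph")
  lmin <- as.integer(min(l_range))
  lmax <- as.integer(max(l_range))
  if (lmin < 2) stop("paths must have at least 2 nodes")
  with_seed(seed,
    cpp_enum_paths(graph_adjacency(graph), lmin, lmax, as.numeric(cap)))
}

#' One-hot encoding of a node-id sequence
#'
#' @param sequence integer vector of node ids (1-based).
#' @param n_nodes vocabulary size.
#' @return an `length(sequence) x n_nodes` binary matrix.
#' @export
one_hot_encode <- function(sequence, n_nodes) {
  sequence <- as.integer(sequence)
  if (any(is.na(sequence)) || any(sequence < 1) || any(sequence > n_nodes))
    stop("node ids must be in 1..n_nodes")
  m <- matrix(0, length(sequence), n_nodes)
  m[cbind(seq_along(sequence), sequence)] <- 1
  m
}

#' @rdname one_hot_encode
#' @param mat a one-hot (or reconstruction) matrix.
#' @return `one_hot_decode`: the integer sequence recovered by row-wise argmax.
#' @export
one_hot_decode <- function(mat) {
  as.integer(apply(mat, 1, which.max))
}

# normalize sequence input (list of vectors or idx/lens pair) to a padded matrix
as_seq_matrix <- function(sequences, l_max) {
  if (is.list(sequences) && !is.null(sequences$idx)) {
    idx <- sequences$idx
    lens <- as.integer(sequences$lens)
  } else {
    if (!is.list(sequences)) stop("`sequences` must be a list of integer vectors")
    lens <- lengths(sequences)
    idx <- matrix(NA_integer_, length(sequences), max(l_max, max(lens, 0L)))
    for (i in seq_along(sequences))
      idx[i, seq_len(lens[i])] <- as.integer(sequences[[i]])
  }
  if (ncol(idx) < l_max)
    idx <- cbind(idx, matrix(NA_integer_, nrow(idx), l_max - ncol(idx)))
  if (any(lens > l_max)) stop("sequences longer than `l_max`")
  if (any(lens < 1)) stop("empty sequence in training set")
  list(idx = idx, lens = lens)
}

#' Train the sequence autoencoder
#'
#' Minimises the mean squared error between the decoder output and the one-hot
#' input (Adam, mini-batches reshuffled each epoch). The per-step encoder
#' hidden states are the low-dimensional codes used downstream.
#'
#' @param sequences either the result of [enumerate_training_sequences()] or a
#'   list of integer node-id vectors.
#' @param config an [encoder_config()].
#' @param verbose print the loss each epoch.
#' @return an object of class `glstm_ae`: list with `weights`, `config` and
#'   `loss_history` (mean squared error per epoch).
#' @examples
#' g <- generate_ba_graph(10, 1, seed = 1)
#' cfg <- encoder_config(10, epochs = 5)
#' set.seed(1)
#' ae <- train_autoencoder(enumerate_training_sequences(g), cfg)
#' ae$loss_history
#' @export
train_autoencoder <- function(sequences, config, verbose = FALSE) {
  stopifnot(inherits(config, "encoder_config"))
  s <- as_seq_matrix(sequences, config$l_max)
  if (nrow(s$idx) < 1) stop("empty training set")
  if (any(s$idx > config$n_nodes, na.rm = TRUE))
    stop("sequence node id exceeds `n_nodes`")
  res <- cpp_ae_train(s$idx, s$lens, config$n_nodes, config$code_dim,
                      config$epochs, config$batch_size, config$learning_rate,
                      NULL)
  if (verbose)
    for (e in seq_along(res$loss))
      message(sprintf("epoch %d: mse %.6g", e, res$loss[e]))
  structure(list(weights = res$weights, config = config,
                 loss_history = as.numeric(res$loss)),
            class = "glstm_ae")
}

#' @export
print.glstm_ae <- function(x, ...) {
  cat(sprintf(
    "Sequence autoencoder: |V| = %d, code dim = %d, trained %d epochs (final mse %.4g)\n",
    x$config$n_nodes, x$config$code_dim, length(x$loss_history),
    if (length(x$loss_history)) x$loss_history[length(x$loss_history)] else NA))
  invisible(x)
}

#' Save / load an autoencoder checkpoint
#'
#' @param ae a `glstm_ae`.
#' @param path file path (`.rds`).
#' @return `path` (save) or the `glstm_ae` (load).
#' @export
save_autoencoder <- function(ae, path) {
  stopifnot(inherits(ae, "glstm_ae"))
  saveRDS(ae, path)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  ae <- readRDS(path)
  stopifnot(inherits(ae, "glstm_ae"))
  ae
}

# encode sequences into padded code slabs, one row per sequence,
# column layout (step-1)*code_dim + code, zero-padded to l_max steps
encode_sequences <- function(ae, sequences, l_max = ae$config$l_max) {
  stopifnot(inherits(ae, "glstm_ae"))
  s <- as_seq_matrix(sequences, l_max)
  cpp_ae_encode(s$idx, s$lens, ae$weights, as.integer(l_max))
}

#' Reconstruct sequences through the autoencoder
#'
#' Encodes each sequence and decodes it back to `|V|`-dimensional rows;
#' useful for measuring reconstruction (argmax) accuracy.
#'
#' @param ae a trained `glstm_ae`.
#' @param sequences list of integer vectors or an `idx`/`lens` pair.
#' @return mean per-step argmax reconstruction accuracy in `[0, 1]`.
#' @export
reconstruction_accuracy <- function(ae, sequences) {
  stopifnot(inherits(ae, "glstm_ae"))
  s <- as_seq_matrix(sequences, ae$config$l_max)
  acc <- cpp_ae_reconstruct_acc(s$idx, s$lens, ae$weights)
  acc
}

#' Encode a snapshot feature into its fixed-shape representation
#'
#' Every sequence is one-hot encoded, passed through the encoder and
#' zero-padded along the step axis to `l_max`; every group is zero-padded with
#' empty slabs to `eta` slots. The result is a `K x eta x l_max x code_dim`
#' numeric array in which all padding entries are exactly zero.
#'
#' @param feature a [snapshot_feature][build_snapshot_feature()].
#' @param ae a trained `glstm_ae`.
#' @return a 4-dimensional array of class `snapshot_representation`.
#' @export
encode_feature <- function(feature, ae) {
  stopifnot(inherits(feature, "snapshot_feature"), inherits(ae, "glstm_ae"))
  if (feature$n_nodes != ae$config$n_nodes)
    stop("feature and autoencoder were built for different graphs")
  K <- length(feature$groups)
  eta <- feature$eta
  l_max <- feature$l_max
  dr <- ae$config$code_dim
  rep <- array(0, dim = c(K, eta, l_max, dr))
  seqs <- unlist(feature$groups, recursive = FALSE)
  if (length(seqs) > 0) {
    if (any(lengths(seqs) > l_max)) stop("sequence longer than `l_max`")
    enc <- encode_sequences(ae, seqs, l_max = l_max)
    i <- 0
    for (g in seq_len(K)) {
      for (s in seq_along(feature$groups[[g]])) {
        i <- i + 1
        rep[g, s, , ] <- matrix(enc[i, ], nrow = l_max, ncol = dr, byrow = TRUE)
      }
    }
  }
  structure(rep, class = "snapshot_representation")
}

# canonical flattening used as classifier input:
# index = (((g-1)*eta + s-1)*l_max + t-1)*code_dim + d
flatten_representation <- function(rep) {
  as.numeric(aperm(unclass(rep), c(4L, 3L, 2L, 1L)))
}

#' @export
print.snapshot_representation <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Snapshot representation: %d x %d x %d x %d (K x eta x l_max x code)\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
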