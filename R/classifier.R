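#' Configuration of the source classification network
#'
#' A two-layer fully connected network over the flattened snapshot
#' representation: input `K * eta * l_max * code_dim`, hidden
#' `K * eta * code_dim` with batch normalisation and ReLU, output `|V|` with a
#' log-softmax. Trained with the cross-entropy between the prediction and the
#' one-hot true source (Adam).
#'
#' @param n_nodes number of candidate sources `|V|`.
#' @param K number of observation areas.
#' @param eta sequences per group.
#' @param l_max maximum sequence length.
#' @param code_dim autoencoder code dimension.
#' @param batch_size,learning_rate,epochs training hyper-parameters.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(n_nodes, K, eta, l_max, code_dim,
                              batch_size = 256L, learning_rate = 0.001,
                              epochs = 20L) {
  structure(list(n_nodes = as.integer(n_nodes), K = as.integer(K),
                 eta = as.integer(eta), l_max = as.integer(l_max),
                 code_dim = as.integer(code_dim),
                 input_dim = as.integer(K * eta * l_max * code_dim),
                 hidden_dim = as.integer(K * eta * code_dim),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs)),
            class = "classifier_config")
}

scnn_init <- function(config) {
  D <- config$input_dim
  H <- config$hidden_dim
  V <- config$n_nodes
  k1 <- 1 / sqrt(D)
  k2 <- 1 / sqrt(H)
  list(W1 = matrix(runif(D * H, -k1, k1), D, H),
       b1 = runif(H, -k1, k1),
       gamma = rep(1, H), beta = rep(0, H),
       run_mean = rep(0, H), run_var = rep(1, H),
       W2 = matrix(runif(H * V, -k2, k2), H, V),
       b2 = runif(V, -k2, k2))
}

# forward pass; train = TRUE uses batch statistics and returns a cache for
# backprop plus updated running statistics, train = FALSE uses running stats
scnn_forward <- function(params, x, train = FALSE, bn_eps = 1e-5,
                         bn_momentum = 0.1) {
  z1 <- sweep(x %*% params$W1, 2, params$b1, "+")
  if (train) {
    B <- nrow(x)
    mu <- colMeans(z1)
    zc <- sweep(z1, 2, mu)
    var_b <- colMeans(zc^2)
    inv_sd <- 1 / sqrt(var_b + bn_eps)
    xhat <- sweep(zc, 2, inv_sd, "*")
    var_unbiased <- if (B > 1) var_b * B / (B - 1) else var_b
    params$run_mean <- (1 - bn_momentum) * params$run_mean + bn_momentum * mu
    params$run_var <- (1 - bn_momentum) * params$run_var + bn_momentum * var_unbiased
  } else {
    xhat <- sweep(sweep(z1, 2, params$run_mean), 2,
                  1 / sqrt(params$run_var + bn_eps), "*")
  }
  bn <- sweep(sweep(xhat, 2, params$gamma, "*"), 2, params$beta, "+")
  a1 <- pmax(bn, 0)
  z2 <- sweep(a1 %*% params$W2, 2, params$b2, "+")
  mx <- apply(z2, 1, max)
  logp <- z2 - mx - log(rowSums(exp(z2 - mx)))
  out <- list(logp = logp, params = params)
  if (train) out$cache <- list(x = x, zc = zc, inv_sd = inv_sd, xhat = xhat,
                               bn = bn, a1 = a1)
  out
}

scnn_loss_grad <- function(params, x, y, bn_eps = 1e-5, bn_momentum = 0.1) {
  B <- nrow(x)
  fw <- scnn_forward(params, x, train = TRUE, bn_eps = bn_eps,
                     bn_momentum = bn_momentum)
  cache <- fw$cache
  loss <- -mean(fw$logp[cbind(seq_len(B), y)])
  dz2 <- exp(fw$logp)
  dz2[cbind(seq_len(B), y)] <- dz2[cbind(seq_len(B), y)] - 1
  dz2 <- dz2 / B
  gW2 <- crossprod(cache$a1, dz2)
  gb2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, params$W2)
  dbn <- da1 * (cache$bn > 0)
  ggamma <- colSums(dbn * cache$xhat)
  gbeta <- colSums(dbn)
  dxhat <- sweep(dbn, 2, params$gamma, "*")
  # batch-norm backward
  dvar <- colSums(dxhat * cache$zc) * (-0.5) * cache$inv_sd^3
  dmu <- colSums(sweep(dxhat, 2, -cache$inv_sd, "*")) +
    dvar * colMeans(-2 * cache$zc)
  dz1 <- sweep(dxhat, 2, cache$inv_sd, "*") +
    sweep(2 * cache$zc, 2, dvar / B, "*") +
    matrix(dmu / B, B, length(dmu), byrow = TRUE)
  gW1 <- crossprod(cache$x, dz1)
  gb1 <- colSums(dz1)
  list(loss = loss, params = fw$params,
       grads = list(W1 = gW1, b1 = gb1, gamma = ggamma, beta = gbeta,
                    W2 = gW2, b2 = gb2))
}

adam_state <- function(params, keys) {
  st <- list(t = 0, m = list(), v = list())
  for (k in keys) {
    st$m[[k]] <- params[[k]] * 0
    st$v[[k]] <- params[[k]] * 0
  }
  st
}

adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (k in names(grads)) {
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * grads[[k]]
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * grads[[k]]^2
    mhat <- st$m[[k]] / (1 - b1^st$t)
    vhat <- st$v[[k]] / (1 - b2^st$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

#' Generate classifier training data by repeated simulation
#'
#' For each of `n_loops` passes, each transmission probability in `betas`, and
#' each node as source, one snapshot is simulated, its feature built and
#' encoded, and the flattened representation stored with the source as label.
#' The resulting design matrix has exactly `n_loops * length(betas) * |V|`
#' rows.
#'
#' @param graph an igraph graph.
#' @param areas [observation_areas][build_observation_areas()] on the same graph.
#' @param ae a trained [glstm_ae][train_autoencoder()].
#' @param n_loops number of passes over (beta, node) combinations.
#' @param betas distinct transmission probabilities in `(0, 1)`; the default
#'   grid is `0.1, 0.2, ..., 0.9`.
#' @param delay a [delay_model()].
#' @param l_max,eta feature construction limits (see
#'   [build_snapshot_feature()]); `eta = NULL` uses [default_eta()].
#' @param single_attempt,edge_delays passed to [simulate_diffusion()].
#' @return an object of class `training_collector`: list with `x` (design
#'   matrix), `y` (integer labels), the feature dimensions and the generation
#'   parameters.
#' @export
generate_training_data <- function(graph, areas, ae, n_loops,
                                   betas = seq(0.1, 0.9, by = 0.1),
                                   delay = delay_model(), l_max = 4,
                                   eta = NULL, single_attempt = FALSE,
                                   edge_delays = NULL, keep_shortest = FALSE) {
  check_graph(graph)
  stopifnot(inherits(areas, "observation_areas"), inherits(ae, "glstm_ae"))
  n <- igraph::vcount(graph)
  if (n != areas$n_nodes) stop("areas built on a different graph")
  if (n != ae$config$n_nodes) stop("autoencoder trained for a different graph (dimension mismatch)")
  if (any(betas <= 0) || any(betas >= 1) || anyDuplicated(betas) > 0)
    stop("`betas` must be distinct values in (0, 1)")
  eta <- eta %||% default_eta(graph)
  K <- length(areas$areas)
  dr <- ae$config$code_dim
  sources <- rep(rep(seq_len(n), times = length(betas)), times = n_loops)
  beta_vec <- rep(rep(betas, each = n), times = n_loops)
  ed <- if (is.null(edge_delays)) NULL else edge_delay_adjacency(graph, edge_delays)
  col <- cpp_collect_features(graph_adjacency(graph), areas$areas,
                              as.integer(sources), beta_vec,
                              delay$mu, delay$sigma, single_attempt, ed,
                              as.integer(l_max), as.integer(eta), keep_shortest)
  n_rec <- length(sources)
  if (length(col$sequences) > 0) {
    enc <- encode_sequences(ae, col$sequences, l_max = l_max)
  } else {
    enc <- matrix(0, 0, l_max * dr)
  }
  x <- cpp_pack_representation(col$placements, enc, n_rec, K,
                               as.integer(eta), as.integer(l_max), dr)
  structure(list(x = x, y = as.integer(sources), beta = beta_vec,
                 n_nodes = n, K = K, eta = as.integer(eta),
                 l_max = as.integer(l_max), code_dim = dr,
                 n_loops = as.integer(n_loops), betas = betas),
            class = "training_collector")
}

#' @export
print.training_collector <- function(x, ...) {
  cat(sprintf(
    "Training collector: %d records (%d loops x %d betas x %d nodes), input dim %d\n",
    nrow(x$x), x$n_loops, length(x$betas), x$n_nodes, ncol(x$x)))
  invisible(x)
}

#' Train the source classification network
#'
#' @param collector a [training_collector][generate_training_data()].
#' @param config a [classifier_config()]; defaults to the dimensions recorded
#'   in the collector with standard training hyper-parameters.
#' @param verbose print the loss each epoch.
#' @return an object of class `scnn`: list with `params`, `config` and
#'   `loss_history` (mean cross-entropy per epoch).
#' @export
train_classifier <- function(collector, config = NULL, verbose = FALSE) {
  stopifnot(inherits(collector, "training_collector"))
  if (nrow(collector$x) == 0) stop("empty training collector")
  config <- config %||% classifier_config(collector$n_nodes, collector$K,
                                          collector$eta, collector$l_max,
                                          collector$code_dim)
  stopifnot(inherits(config, "classifier_config"))
  if (ncol(collector$x) != config$input_dim)
    stop("collector input dimension does not match the classifier configuration")
  if (config$n_nodes != collector$n_nodes)
    stop("label space does not match the classifier configuration")
  params <- scnn_init(config)
  st <- adam_state(params, c("W1", "b1", "gamma", "beta", "W2", "b2"))
  nrec <- nrow(collector$x)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nrec)
    total <- 0
    for (start in seq(1, nrec, by = config$batch_size)) {
      idx <- ord[start:min(nrec, start + config$batch_size - 1)]
      lg <- scnn_loss_grad(params, collector$x[idx, , drop = FALSE],
                           collector$y[idx])
      params <- lg$params  # running BN statistics were updated
      stp <- adam_step(params, lg$grads, st, config$learning_rate)
      params <- stp$params
      st <- stp$state
      total <- total + lg$loss * length(idx)
    }
    losses[ep] <- total / nrec
    if (verbose) message(sprintf("epoch %d: cross-entropy %.5g", ep, losses[ep]))
  }
  structure(list(params = params, config = config, loss_history = losses),
            class = "scnn")
}

#' @export
print.scnn <- function(x, ...) {
  cat(sprintf(
    "Source classifier: input %d -> hidden %d -> %d classes; trained %d epochs (final loss %.4g)\n",
    x$config$input_dim, x$config$hidden_dim, x$config$n_nodes,
    length(x$loss_history),
    if (length(x$loss_history)) x$loss_history[length(x$loss_history)] else NA))
  invisible(x)
}

#' Save / load a classifier checkpoint
#'
#' @param classifier an `scnn`.
#' @param path file path (`.rds`).
#' @return `path` (save) or the `scnn` (load).
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "scnn"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  stopifnot(inherits(clf, "scnn"))
  clf
}

#' Identify the diffusion source of a snapshot
#'
#' Runs the full inference chain: feature construction, autoencoder encoding,
#' and classification (in evaluation mode, so batch normalisation uses its
#' running statistics and single snapshots work). The estimate is the argmax
#' of the class scores, ties broken by smallest node id.
#'
#' @param snapshot a [diffusion_snapshot][simulate_diffusion()].
#' @param areas the `observation_areas` used during training.
#' @param ae the trained `glstm_ae`.
#' @param classifier the trained `scnn`.
#' @return an object of class `source_estimate`: list with `estimate` (node
#'   id) and `scores` (log-probability per candidate node).
#' @export
identify_source <- function(snapshot, areas, ae, classifier) {
  stopifnot(inherits(snapshot, "diffusion_snapshot"),
            inherits(areas, "observation_areas"),
            inherits(ae, "glstm_ae"), inherits(classifier, "scnn"))
  cfg <- classifier$config
  feature <- build_snapshot_feature(snapshot, areas, l_max = cfg$l_max,
                                    eta = cfg$eta)
  rep <- encode_feature(feature, ae)
  x <- matrix(flatten_representation(rep), nrow = 1)
  if (ncol(x) != cfg$input_dim)
    stop("representation does not match the classifier input dimension")
  fw <- scnn_forward(classifier$params, x, train = FALSE)
  scores <- as.numeric(fw$logp)
  structure(list(estimate = which.max(scores), scores = scores),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  top <- order(-x$scores)[seq_len(min(5, length(x$scores)))]
  cat(sprintf("Estimated source: node %d\n", x$estimate))
  cat("Top candidates (log-probability):\n")
  for (v in top) cat(sprintf("  node %d: %.4f\n", v, x$scores[v]))
  invisible(x)
}
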