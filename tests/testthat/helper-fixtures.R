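# Shared fixtures, built once per test run.

# hand-built snapshot for feature-construction tests
make_snapshot <- function(n, source, time, infector, beta = 0.5) {
  structure(list(source = as.integer(source), beta = beta,
                 time = as.numeric(time), infector = as.integer(infector),
                 n_nodes = as.integer(n), mu = 4, sigma = 1),
            class = "diffusion_snapshot")
}

# path graph 1-2-...-n as igraph
path_graph <- function(n) {
  igraph::make_graph(as.integer(rbind(1:(n - 1), 2:n)), directed = FALSE)
}

# small trained end-to-end fixture: 20-node scale-free graph, 2 observation
# areas, autoencoder + classifier trained under fixed seeds
fixture_models <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- generate_ba_graph(20, 2, 1, seed = 42)
    vital <- select_vital_nodes(g, 0.1)
    areas <- build_observation_areas(g, vital, h = 1)
    eta <- default_eta(g)
    ed <- sample_edge_delays(g, seed = 43)
    set.seed(1001)
    corpus <- enumerate_training_sequences(g, 2:4)
    ae <- train_autoencoder(corpus, encoder_config(20, epochs = 60))
    collector <- generate_training_data(g, areas, ae, n_loops = 20,
                                        betas = c(0.3, 0.6, 0.9),
                                        l_max = 4, eta = eta,
                                        edge_delays = ed)
    clf <- train_classifier(collector,
                            classifier_config(20, length(areas$areas), eta, 4,
                                              ae$config$code_dim,
                                              batch_size = 64, epochs = 20))
    cache <<- list(graph = g, areas = areas, eta = eta, corpus = corpus,
                   edge_delays = ed, ae = ae, collector = collector,
                   classifier = clf)
    cache
  }
})
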