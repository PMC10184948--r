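required_config_fields <- list(
  graph = c("type"),
  areas = c("fraction", "h"),
  delay = c("mu", "sigma"),
  features = c("l_max"),
  encoder = c("batch_size", "learning_rate", "epochs"),
  classifier = c("n_loops", "batch_size", "learning_rate", "epochs"),
  eval = c("n_seeds", "betas"),
  seeds = c("graph", "train", "eval")
)

validate_config <- function(config) {
  missing <- character(0)
  for (sec in names(required_config_fields)) {
    if (is.null(config[[sec]])) {
      missing <- c(missing, sec)
      next
    }
    for (f in required_config_fields[[sec]])
      if (is.null(config[[sec]][[f]])) missing <- c(missing, paste(sec, f, sep = "."))
  }
  if (length(missing) > 0)
    stop("missing config fields: ", paste(missing, collapse = ", "))
  invisible(config)
}

build_config_graph <- function(gcfg, seed) {
  switch(gcfg$type,
    ba = generate_ba_graph(gcfg$n, gcfg$m, gcfg$power %||% 1, seed = seed),
    ws = generate_ws_graph(gcfg$n, gcfg$nei, gcfg$p, seed = seed),
    edgelist = read_edge_list(gcfg$path),
    stop("unknown graph type: ", gcfg$type)
  )
}

#' Load a bundled experiment preset
#'
#' Presets `ba1`, `ba2`, `ws1` and `ws2` configure the synthetic scale-free
#' and small-world study networks (400 and 1000 nodes) with their full
#' training schedules.
#'
#' @param name preset name, or a path to a YAML config file.
#' @return a config list suitable for [run_experiment()].
#' @export
preset_config <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("presets", paste0(name, ".yaml"), package = "netsource")
  if (!nzchar(path) || !file.exists(path)) stop("unknown preset or file: ", name)
  validate_config(yaml::read_yaml(path))
}

#' Run a complete source-identification experiment
#'
#' Builds (or loads) the network, places observers, trains the sequence
#' autoencoder and the source classifier, evaluates identification accuracy
#' on fresh test snapshots, and optionally writes all artifacts: model
#' checkpoints, the per-seed evaluation table (`eval.csv`), a JSON summary
#' (`summary.json`) and a reproducibility manifest (`manifest.json`) with all
#' parameters and seeds.
#'
#' @param config a config list, a preset name, or a YAML file path. Sections:
#'   `graph` (type `ba`/`ws`/`edgelist` with parameters), `areas` (`fraction`,
#'   `h`), `delay` (`mu`, `sigma`), `features` (`l_max`, optional `eta`),
#'   `encoder` and `classifier` (training schedules; `classifier` also takes
#'   `n_loops` and optional `betas`), `eval` (`n_seeds`, `betas`), `seeds`
#'   (`graph`, `train`, `eval`).
#' @param out_dir directory for artifacts; `NULL` writes nothing.
#' @param verbose print stage progress.
#' @return a list with `graph`, `areas`, `ae`, `classifier`, `eval`,
#'   `summary` and `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- preset_config(config)
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))

  say("building graph (%s)", config$graph$type)
  graph <- build_config_graph(config$graph, config$seeds$graph)
  n <- igraph::vcount(graph)

  vital <- select_vital_nodes(graph, config$areas$fraction)
  areas <- build_observation_areas(graph, vital, config$areas$h)
  l_max <- config$features$l_max
  eta <- config$features$eta %||% default_eta(graph)
  delay <- delay_model(config$delay$mu, config$delay$sigma)
  # per-edge delays are part of the network: drawn once, shared by all runs
  per_edge <- config$delay$per_edge %||% TRUE
  edge_delays <- if (per_edge)
    sample_edge_delays(graph, delay, seed = config$seeds$graph + 1L) else NULL
  betas <- config$classifier$betas %||% seq(0.1, 0.9, by = 0.1)

  set.seed(config$seeds$train)
  say("enumerating training sequences")
  corpus <- enumerate_training_sequences(graph, l_range = 2:l_max,
                                         cap = config$encoder$cap %||% Inf)
  enc_cfg <- encoder_config(n, code_dim = config$encoder$code_dim,
                            l_max = l_max,
                            batch_size = config$encoder$batch_size,
                            learning_rate = config$encoder$learning_rate,
                            epochs = config$encoder$epochs)
  say("training autoencoder on %d sequences", length(corpus$lens))
  ae <- train_autoencoder(corpus, enc_cfg, verbose = verbose)

  say("generating classifier training data (%d records)",
      config$classifier$n_loops * length(betas) * n)
  collector <- generate_training_data(graph, areas, ae,
                                      n_loops = config$classifier$n_loops,
                                      betas = betas, delay = delay,
                                      l_max = l_max, eta = eta,
                                      edge_delays = edge_delays)
  clf_cfg <- classifier_config(n, length(areas$areas), eta, l_max,
                               enc_cfg$code_dim,
                               batch_size = config$classifier$batch_size,
                               learning_rate = config$classifier$learning_rate,
                               epochs = config$classifier$epochs)
  say("training classifier")
  classifier <- train_classifier(collector, clf_cfg, verbose = verbose)

  set.seed(config$seeds$eval)
  say("evaluating on %d test sources", config$eval$n_seeds)
  ev <- evaluate_pipeline(graph, areas, ae, classifier,
                          n_seeds = config$eval$n_seeds,
                          betas = config$eval$betas, delay = delay,
                          edge_delays = edge_delays)

  summary <- list(precision = ev$precision, avg_error = ev$avg_error,
                  histogram = as.list(setNames(as.integer(ev$histogram),
                                               names(ev$histogram))))
  manifest <- list(
    package_version = as.character(utils::packageVersion("netsource")),
    graph = config$graph,
    n_nodes = n, n_edges = igraph::ecount(graph),
    K = length(areas$areas), n_observers = length(areas$observers),
    h = config$areas$h, l_max = l_max, eta = eta,
    delay = list(mu = delay$mu, sigma = delay$sigma, per_edge = per_edge),
    encoder = list(code_dim = enc_cfg$code_dim, corpus_size = length(corpus$lens),
                   batch_size = enc_cfg$batch_size,
                   learning_rate = enc_cfg$learning_rate, epochs = enc_cfg$epochs),
    classifier = list(n_loops = config$classifier$n_loops, betas = betas,
                      dataset_size = nrow(collector$x),
                      input_dim = clf_cfg$input_dim,
                      hidden_dim = clf_cfg$hidden_dim,
                      batch_size = clf_cfg$batch_size,
                      learning_rate = clf_cfg$learning_rate,
                      epochs = clf_cfg$epochs),
    eval = list(n_seeds = config$eval$n_seeds, betas = config$eval$betas),
    seeds = config$seeds
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_edge_list(graph, file.path(out_dir, "graph.edgelist"))
    if (per_edge)
      writeLines(format(edge_delays, digits = 17),
                 file.path(out_dir, "edge_delays.txt"))
    write_area_set(areas, file.path(out_dir, "areas.txt"))
    save_autoencoder(ae, file.path(out_dir, "encoder.rds"))
    save_classifier(classifier, file.path(out_dir, "classifier.rds"))
    write.csv(ev$records, file.path(out_dir, "eval.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(graph = graph, areas = areas, ae = ae,
                 classifier = classifier, eval = ev, summary = summary,
                 manifest = manifest))
}
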