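# netsource

Identify the source of a spreading process on a network — a rumor, an
epidemic, a computer virus — from the direction and timing information
recorded by a limited set of observer nodes.

## The problem and the method

A cascade starts at a single unknown node of a known undirected network
`G = {V, E, θ}` and spreads along its edges: an informed node `v` transmits to
each neighbour `u` with per-contact success probability `β`, a successful
contact arriving after the edge's propagation delay `θ_vu` (Gaussian with
`μ/σ = 4`, truncated positive, drawn once per network); failed contacts retry
after a further edge delay, so the process ends only when no reachable node is
ignorant. Afterwards we see, for the observers only, each node's informed
time `t_v` and its *infector* — the neighbour it received the information
from. The task: estimate the source `s* = argmax_v P(v | observations)`.

netsource casts this as classification in three stages:

1. **Observation areas and snapshot features.** The top `⌈0.01·|V|⌉` nodes by
   degree centrality become *vital nodes*; each plus its `h = 1`-hop
   neighbourhood is an observation area `A_i`. From a snapshot `S`, the
   infector chain of every observer is traced backwards inside its area into
   node-id sequences of length 2..`l_max`; per area the `η = 2⌈⟨k⟩⌉` longest
   distinct chains are kept, and areas are ordered by mean informed time.
   This is the snapshot feature `F(S)` — `K` groups of sequences.
2. **Sequence autoencoder.** An LSTM encoder maps each sequence of `|V|`-dim
   one-hot vectors to per-step codes `r ∈ R^{|seq| × d_r}` (`d_r` = 8 or 16);
   an LSTM decoder with a linear head reconstructs the input, trained with
   mean-squared error on directed simple paths enumerated from `G`. Codes are
   zero-padded into the fixed block `R(S) ∈ R^{K × η × l_max × d_r}`.
3. **Source classifier.** A two-layer fully connected network
   (`K·η·l_max·d_r → K·η·d_r` with batch-norm and ReLU, then `→ |V|` with
   log-softmax, cross-entropy loss) trained on simulated cascades from every
   node under the β grid `0.1 … 0.9`; `ŝ = argmax` of its output.

Accuracy is reported as *precision* (fraction of test cascades whose estimate
has zero hop error) and *average error distance* (mean shortest-path hops
between estimate and truth).

## Worked example

```r
library(netsource)

g     <- generate_ba_graph(50, m = 2, power = 1.3, seed = 1)
theta <- sample_edge_delays(g, delay_model(mu = 4, sigma = 1), seed = 2)
areas <- build_observation_areas(g, select_vital_nodes(g, 0.05), h = 1)

set.seed(3)
ae         <- train_autoencoder(enumerate_training_sequences(g, 2:4),
                                encoder_config(50, epochs = 40))
collector  <- generate_training_data(g, areas, ae, n_loops = 10,
                                     edge_delays = theta)
classifier <- train_classifier(collector)

set.seed(4)
snap <- simulate_diffusion(g, source = 17, beta = 0.7, edge_delays = theta)
identify_source(snap, areas, ae, classifier)
#> Estimated source: node 17
#> Top candidates (log-probability):
#>   node 17: -0.6731
#>   node 49: -0.8047
#>   node 23: -4.8315

set.seed(5)
evaluate_pipeline(g, areas, ae, classifier, n_seeds = 50, edge_delays = theta)
#> Pipeline evaluation over 50 test sources:
#>   precision (0-hop): 50.0%
#>   average error: 1.100 hops
#>   error histogram: 0:25  1:6  2:10  3:7  4:2
```

The cascade started at node 17; the classifier's top candidate is node 17
with log-probability −0.67 (posterior ≈ 0.51). Over 50 fresh test cascades
with β drawn uniformly from the training grid, half the sources are hit
exactly and the mean miss distance is 1.1 hops — against a 2% chance baseline
for 50 candidate nodes.

Full-scale experiments are driven by bundled presets
(`run_experiment("ba1")`, similarly `ba2`, `ws1`, `ws2`), which build the
400- or 1000-node study networks, train both models at their schedules, and
write checkpoints, per-seed results and a reproducibility manifest. A thin
command-line front end is installed at `inst/cli/netsource`
(`netsource evaluate --config ba1.yaml`, `netsource identify ...`).

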