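name: ba2
graph: {type: ba, "n": 1000, m: 2, power: 1.3}
areas: {fraction: 0.01, h: 1}
delay: {mu: 4.0, sigma: 1.0}
features: {l_max: 4}
encoder: {batch_size: 1024, learning_rate: 0.01, epochs: 10}
classifier: {n_loops: 6, batch_size: 1024, learning_rate: 0.0001, epochs: 20}
eval:
  n_seeds: 100
  betas: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
seeds: {graph: 101, train: 202, eval: 303}
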