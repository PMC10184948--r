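test_that("path corpus enumeration matches brute-force counts on small graphs", {
  tri <- igraph::make_graph(c(1,2, 2,3, 3,1), directed = FALSE)
  s2 <- enumerate_training_sequences(tri, l_range = 2)
  expect_length(s2$lens, 6)  # ordered adjacent pairs

  pg <- path_graph(3)
  s3 <- enumerate_training_sequences(pg, l_range = 3)
  expect_length(s3$lens, 2)
  got <- lapply(seq_len(nrow(s3$idx)), function(i) s3$idx[i, 1:3])
  expect_true(list(c(1L, 2L, 3L)) %in% got && list(c(3L, 2L, 1L)) %in% got)

  capped <- enumerate_training_sequences(generate_ba_graph(30, 2, 1, seed = 1),
                                         cap = 5, seed = 2)
  expect_lte(length(capped$lens), 5)
  # sampled paths are still simple directed paths on the graph
  g <- generate_ba_graph(30, 2, 1, seed = 1)
  for (i in seq_along(capped$lens)) {
    s <- capped$idx[i, seq_len(capped$lens[i])]
    expect_identical(anyDuplicated(s), 0L)
    for (j in seq_len(length(s) - 1))
      expect_true(igraph::are_adjacent(g, s[j], s[j + 1]))
  }
})

test_that("one-hot encoding and argmax decoding are inverses", {
  m <- one_hot_encode(c(3, 1), 3)
  expect_identical(m, rbind(c(0, 0, 1), c(1, 0, 0)))
  expect_identical(rowSums(m), c(1, 1))
  expect_identical(one_hot_decode(m), c(3L, 1L))
  expect_error(one_hot_encode(c(1, 5), 3), "1..n_nodes", fixed = TRUE)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(31)
  w <- netsource:::cpp_ae_init(6, 3)
  idx <- rbind(c(2L, 4L, NA, NA), c(1L, 3L, 6L, 5L), c(6L, 2L, NA, NA))
  lens <- c(2L, 4L, 2L)
  gr <- netsource:::cpp_ae_grad(idx, lens, w)
  eps <- 1e-6
  for (nm in setdiff(names(gr), "loss")) {
    ks <- sample(length(w[[nm]]), min(8, length(w[[nm]])))
    for (k in ks) {
      w2 <- w
      w2[[nm]][k] <- w2[[nm]][k] + eps
      up <- netsource:::cpp_ae_loss(idx, lens, w2)
      w2[[nm]][k] <- w2[[nm]][k] - 2 * eps
      dn <- netsource:::cpp_ae_loss(idx, lens, w2)
      expect_equal(gr[[nm]][k], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training reduces reconstruction error and beats chance accuracy", {
  g <- path_graph(10)
  corpus <- enumerate_training_sequences(g, 2:4)
  set.seed(32)
  ae <- train_autoencoder(corpus, encoder_config(10, epochs = 200))
  expect_lt(ae$loss_history[length(ae$loss_history)], ae$loss_history[1])
  expect_gt(reconstruction_accuracy(ae, corpus), 1 / 10)
})

test_that("the code dimension follows the network-size rule", {
  expect_equal(encoder_config(400)$code_dim, 8)
  expect_equal(encoder_config(1000)$code_dim, 16)
  expect_equal(encoder_config(1000, code_dim = 8)$code_dim, 8)
})

test_that("per-step codes have one row per sequence element, zero beyond", {
  set.seed(33)
  ae <- structure(list(weights = netsource:::cpp_ae_init(400, 8),
                       config = encoder_config(400), loss_history = numeric(0)),
                  class = "glstm_ae")
  enc <- netsource:::encode_sequences(ae, list(c(5L, 17L, 300L)))
  expect_identical(dim(enc), c(1L, 32L))  # l_max * code_dim
  m <- matrix(enc[1, ], nrow = 4, byrow = TRUE)   # 4 steps x 8 codes
  expect_true(all(m[1:3, ] != 0))
  expect_identical(m[4, ], rep(0, 8))
})

test_that("feature encoding obeys the shape and exact-zero padding contracts", {
  set.seed(34)
  ae <- structure(list(weights = netsource:::cpp_ae_init(20, 8),
                       config = encoder_config(20), loss_history = numeric(0)),
                  class = "glstm_ae")
  feature <- structure(list(
    groups = list(list(c(1L, 2L), c(2L, 3L, 4L)), list()),
    area_order = 1:2, l_max = 4L, eta = 5L, n_nodes = 20L),
    class = "snapshot_feature")
  rep <- encode_feature(feature, ae)
  expect_identical(dim(rep), c(2L, 5L, 4L, 8L))
  # rows beyond each sequence length are exactly zero
  expect_identical(rep[1, 1, 3:4, ], matrix(0, 2, 8))
  expect_identical(rep[1, 2, 4, ], rep(0, 8))
  expect_true(all(rep[1, 2, 1:3, ] != 0))
  # group slots beyond the stored sequences are exactly zero
  expect_identical(sum(abs(rep[1, 3:5, , ])), 0)
  # empty group is an all-zero slab block
  expect_identical(sum(abs(rep[2, , , ])), 0)

  empty <- structure(list(groups = list(list(), list()), area_order = 1:2,
                          l_max = 4L, eta = 5L, n_nodes = 20L),
                     class = "snapshot_feature")
  rep0 <- encode_feature(empty, ae)
  expect_identical(dim(rep0), c(2L, 5L, 4L, 8L))
  expect_identical(sum(abs(rep0)), 0)
})

test_that("encoding is deterministic and checkpoints restore it exactly", {
  fx <- fixture_models()
  seqs <- list(c(1L, 2L, 3L), c(4L, 5L))
  e1 <- netsource:::encode_sequences(fx$ae, seqs)
  e2 <- netsource:::encode_sequences(fx$ae, seqs)
  expect_identical(e1, e2)
  p <- withr::local_tempfile(fileext = ".rds")
  save_autoencoder(fx$ae, p)
  expect_identical(netsource:::encode_sequences(load_autoencoder(p), seqs), e1)
})
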