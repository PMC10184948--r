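test_that("truncated Gaussian delays have the right mean and stay positive", {
  set.seed(1)
  d <- sample_delay(delay_model(4, 1), 1e5)
  expect_true(all(d > 0))
  # truncation at mu/sigma = 4 shifts the mean by < 1e-4
  expect_equal(mean(d), 4, tolerance = 0.02 / 4)

  tiny <- sample_delay(delay_model(1, 1e-9), 100)
  expect_equal(tiny, rep(1, 100), tolerance = 1e-6)
})

test_that("hand-traced spreading on a path graph", {
  g <- path_graph(3)
  set.seed(2)
  s <- simulate_diffusion(g, 1, beta = 1, delay_model(mu = 1, sigma = 1e-9))
  expect_equal(s$time, c(0, 1, 2), tolerance = 1e-6)
  expect_identical(s$infector, c(NA_integer_, 1L, 2L))
})

test_that("beta = 0 informs only the source; beta > 0 reaches every node by default", {
  g <- generate_ba_graph(50, 2, 1, seed = 4)
  set.seed(1)
  s <- simulate_diffusion(g, 10, beta = 0)
  expect_identical(which(!is.na(s$time)), 10L)
  expect_true(all(is.na(s$infector)))
  # retry-until-success terminates only when no node is ignorant
  set.seed(2)
  s2 <- simulate_diffusion(g, 10, beta = 0.1)
  expect_true(all(!is.na(s2$time)))
})

test_that("informed times equal Dijkstra distances on the recorded contact delays", {
  for (seed in 1:4) {
    g <- if (seed %% 2) generate_ba_graph(100, 2, 1.3, seed = seed) else
      generate_ws_graph(100, 2, 0.1, seed = seed)
    set.seed(seed + 100)
    src <- sample.int(100, 1)
    beta <- if (seed <= 2) 1 else 0.6  # effective delays make the oracle exact at any beta
    s <- simulate_diffusion(g, src, beta = beta, record_contacts = TRUE)
    dg <- igraph::graph_from_edgelist(s$contacts[, 1:2], directed = TRUE)
    d <- igraph::distances(dg, v = src, mode = "out", weights = s$contacts[, 3])
    expect_equal(s$time, as.numeric(d[1, ]), tolerance = 1e-10)
  }
})

test_that("infector pointers form a time-increasing tree rooted at the source", {
  g <- generate_ba_graph(80, 2, 1.2, seed = 6)
  for (seed in 1:10) {
    set.seed(seed)
    src <- sample.int(80, 1)
    s <- simulate_diffusion(g, src, beta = 0.5,
                            single_attempt = seed %% 2 == 0)
    informed <- which(!is.na(s$time))
    expect_true(src %in% informed)
    expect_equal(s$time[src], 0)
    expect_equal(min(s$time, na.rm = TRUE), 0)
    others <- setdiff(informed, src)
    for (v in others) {
      w <- s$infector[v]
      expect_false(is.na(w))
      expect_true(w %in% informed)
      expect_true(igraph::are_adjacent(g, w, v))
      expect_lt(s$time[w], s$time[v])
    }
    # ignorant nodes have no infector; following pointers reaches the source
    expect_true(all(is.na(s$infector[setdiff(1:80, informed)])))
    for (v in others) {
      c <- v
      for (i in 1:81) {
        c <- s$infector[c]
        if (is.na(c)) break
      }
      expect_true(is.na(c))
    }
  }
})

test_that("expected informed fraction is non-decreasing in beta", {
  g <- generate_ba_graph(100, 2, 1.3, seed = 8)
  # single-attempt cascades grow strictly with beta ...
  frac <- sapply(c(0.1, 0.5, 0.9), function(b) {
    set.seed(123)
    mean(replicate(200, sum(!is.na(
      simulate_diffusion(g, 1, b, single_attempt = TRUE)$time)) / 100))
  })
  expect_true(all(diff(frac) > 0))
  # ... and the retry model is their beta -> 1 envelope: full coverage throughout
  frac_retry <- sapply(c(0.1, 0.5, 0.9), function(b) {
    set.seed(123)
    mean(replicate(20, sum(!is.na(simulate_diffusion(g, 1, b)$time)) / 100))
  })
  expect_true(all(diff(frac_retry) >= 0))
  expect_equal(frac_retry[1], 1)
})

test_that("identical seed reproduces the identical snapshot", {
  g <- generate_ws_graph(60, 2, 0.1, seed = 9)
  set.seed(77)
  s1 <- simulate_diffusion(g, 5, 0.4)
  set.seed(77)
  s2 <- simulate_diffusion(g, 5, 0.4)
  set.seed(78)
  s3 <- simulate_diffusion(g, 5, 0.4, single_attempt = TRUE)
  set.seed(78)
  s4 <- simulate_diffusion(g, 5, 0.4, single_attempt = TRUE)
  expect_identical(s3$time, s4$time)
  expect_identical(s1$time, s2$time)
  expect_identical(s1$infector, s2$infector)
})

test_that("snapshot serialization round-trips", {
  g <- generate_ba_graph(30, 2, 1, seed = 10)
  set.seed(3)
  s <- simulate_diffusion(g, 4, 0.6)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_snapshot(s, p)
  s2 <- read_snapshot(p)
  expect_equal(s2$time, s$time)
  expect_identical(s2$infector, s$infector)
  expect_identical(s2$source, s$source)
  expect_equal(s2$beta, s$beta)
})

test_that("simulation rejects invalid sources and probabilities", {
  g <- path_graph(5)
  expect_error(simulate_diffusion(g, 9, 0.5), "1..|V|", fixed = TRUE)
  expect_error(simulate_diffusion(g, 1, 1.2), "beta")
})
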