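test_that("scale-free generator follows the two-node-seed edge-count closed form", {
  for (case in list(c(10, 1), c(50, 2), c(400, 2))) {
    g <- generate_ba_graph(case[1], case[2], power = 1.2, seed = 7)
    expect_equal(igraph::ecount(g), 1 + case[2] * (case[1] - 2))
    expect_true(igraph::is_connected(g))
    expect_true(igraph::is_simple(g))
  }
  # for m > 2 the early nodes can only attach to the nodes already present
  g3 <- generate_ba_graph(200, 3, power = 1.2, seed = 7)
  expect_equal(igraph::ecount(g3), sum(pmin(3, 0:199)))
  expect_equal(igraph::ecount(generate_ba_graph(2, 1, seed = 1)), 1)
  expect_error(generate_ba_graph(1, 1), "at least 2")
  expect_error(generate_ba_graph(5, 5), "m < n")
})

test_that("small-world generator keeps |E| = n * nei and p = 0 gives the lattice", {
  g <- generate_ws_graph(100, 2, 0.1, seed = 3)
  expect_equal(igraph::ecount(g), 200)
  expect_true(igraph::is_simple(g))
  lattice <- generate_ws_graph(30, 2, 0, seed = 1)
  expect_true(all(igraph::degree(lattice) == 4))
  expect_error(generate_ws_graph(100, 2, 1.5), "probability")
  expect_error(generate_ws_graph(4, 2, 0.1), "exceed")
})

test_that("generation is deterministic under a fixed seed and leaves the RNG stream alone", {
  g1 <- generate_ba_graph(60, 2, 1.3, seed = 11)
  set.seed(99)
  before <- runif(1)
  g2 <- generate_ba_graph(60, 2, 1.3, seed = 11)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  set.seed(99)
  expect_identical(before, runif(1))
})

test_that("edge-list io relabels in first-appearance order, deduplicates, rejects loops", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a b", "b c"), p)
  g <- read_edge_list(p)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_identical(igraph::V(g)$name, c("a", "b", "c"))

  writeLines(c("a b", "a b"), p)
  expect_equal(igraph::ecount(read_edge_list(p)), 1)

  writeLines("a a", p)
  expect_error(read_edge_list(p), "self-loop")

  writeLines("a b c", p)
  expect_error(read_edge_list(p), "line 1")

  # round trip reproduces an isomorphic graph: mapping labels back to the
  # original ids recovers the identical edge set
  g <- generate_ws_graph(40, 2, 0.2, seed = 5)
  write_edge_list(g, p)
  g2 <- read_edge_list(p)
  orig <- as.integer(igraph::V(g2)$name)
  el2 <- igraph::as_edgelist(g2, names = FALSE)
  back <- cbind(orig[el2[, 1]], orig[el2[, 2]])
  canon <- function(m) {
    m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    m[order(m[, 1], m[, 2]), ]
  }
  expect_equal(canon(back), canon(igraph::as_edgelist(g, names = FALSE)))
})

test_that("largest component extraction reindexes and breaks ties by smallest index", {
  # two triangles and an isolated node; tie broken toward nodes 1:3
  g <- igraph::make_graph(c(1,2, 2,3, 3,1, 4,5, 5,6, 6,4), directed = FALSE)
  g <- igraph::add_vertices(g, 1)
  lcc <- largest_component(g)
  expect_equal(igraph::vcount(lcc), 3)
  expect_equal(igraph::ecount(lcc), 3)

  # path(4) u path(2): BFS component enumeration picks the 4-node path
  g <- igraph::make_graph(c(1,2, 2,3, 3,4, 5,6), directed = FALSE)
  lcc <- largest_component(g)
  expect_equal(igraph::vcount(lcc), 4)
  expect_equal(sort(igraph::degree(lcc)), c(1, 1, 2, 2))

  g <- generate_ba_graph(30, 1, seed = 2)
  expect_identical(igraph::as_edgelist(largest_component(g)),
                   igraph::as_edgelist(g))
})

test_that("topology summary matches direct degree arithmetic", {
  tri <- igraph::make_graph(c(1,2, 2,3, 3,1), directed = FALSE)
  ts <- topology_summary(tri)
  expect_equal(ts$avg_degree, 2)
  expect_equal(ts$heterogeneity, 1)
  expect_equal(ts$avg_path_length, 1)

  star <- igraph::make_graph(c(1,2, 1,3, 1,4), directed = FALSE)
  ts <- topology_summary(star)
  expect_equal(ts$avg_degree, 1.5)
  expect_equal(ts$heterogeneity, ((9 + 1 + 1 + 1) / 4) / 1.5^2)

  ws <- generate_ws_graph(400, 2, 0.1, seed = 1)
  expect_equal(topology_summary(ws)$avg_degree, 4, tolerance = 1e-12)
})

test_that("degree heterogeneity is >= 1 with equality only for regular graphs", {
  for (s in 1:5) {
    g <- generate_ba_graph(40, 2, 1.1, seed = s)
    expect_gte(topology_summary(g)$heterogeneity, 1)
  }
  expect_equal(topology_summary(generate_ws_graph(50, 2, 0, seed = 1))$heterogeneity, 1)
})
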