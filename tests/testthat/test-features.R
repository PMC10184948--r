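# independent R re-implementation of the feature construction, used as an
# oracle against the C++ path
r_feature_oracle <- function(snap, areas, l_max, eta) {
  key <- sapply(areas$areas, function(a) {
    t <- snap$time[a]
    if (all(is.na(t))) Inf else mean(t, na.rm = TRUE)
  })
  ord <- order(key)  # stable in R
  groups <- lapply(ord, function(ai) {
    area <- areas$areas[[ai]]
    seqs <- list()
    for (o in area) {
      s <- integer(0)
      c <- o
      while (!is.na(c) && c %in% area && !is.na(snap$time[c])) {
        s <- c(s, c)
        c <- snap$infector[c]
      }
      s <- rev(s)
      if (length(s) > l_max) s <- s[seq_len(l_max)]
      if (length(s) >= 2) seqs[[length(seqs) + 1]] <- s
    }
    seqs <- unique(seqs)
    if (length(seqs) > 1) {
      # length-descending, ties by lexicographic node order (selection sort)
      cmp <- function(a, b) {
        if (length(a) != length(b)) return(length(a) > length(b))
        for (i in seq_along(a)) if (a[i] != b[i]) return(a[i] < b[i])
        FALSE
      }
      n <- length(seqs)
      for (i in seq_len(n - 1))
        for (j in seq(i + 1, n))
          if (cmp(seqs[[j]], seqs[[i]])) { tmp <- seqs[[i]]; seqs[[i]] <- seqs[[j]]; seqs[[j]] <- tmp }
    }
    seqs[seq_len(min(eta, length(seqs)))]
  })
  list(groups = groups, area_order = ord)
}

toy_areas <- function(n, areas, h = 1) {
  structure(list(areas = lapply(areas, as.integer),
                 vital_nodes = vapply(areas, function(a) as.integer(a[1]), 1L),
                 h = as.integer(h),
                 observers = sort(unique(unlist(areas))), n_nodes = as.integer(n)),
            class = "observation_areas")
}

test_that("tracing follows the infector chain, reverses, and needs 2+ nodes", {
  snap <- make_snapshot(3, 1, c(0, 1, 2), c(NA, 1, 2))
  expect_identical(trace_sequence(snap, 1:3, observer = 3), c(1L, 2L, 3L))
  # ignorant observer yields nothing
  snap2 <- make_snapshot(3, 1, c(0, 1, NA), c(NA, 1, NA))
  expect_null(trace_sequence(snap2, 1:3, observer = 3))
  # chain leaving the area stops at the boundary
  snap3 <- make_snapshot(4, 1, c(0, 1, 2, 3), c(NA, 1, 2, 3))
  expect_identical(trace_sequence(snap3, c(3, 4), observer = 4), c(3L, 4L))
  expect_error(trace_sequence(snap, c(1, 2), observer = 3), "belong")
})

test_that("over-long chains keep the earliest-informed l_max nodes", {
  snap <- make_snapshot(6, 1, 0:5, c(NA, 1:5))
  expect_identical(trace_sequence(snap, 1:6, observer = 6, l_max = 4),
                   c(1L, 2L, 3L, 4L))
})

test_that("duplicate traced chains collapse and groups trim to the eta longest", {
  # truncation makes observers 4, 5 and 6 share the chain 1-2-3-4
  snap <- make_snapshot(6, 1, 0:5, c(NA, 1:5))
  f <- build_snapshot_feature(snap, toy_areas(6, list(1:6)), l_max = 4, eta = 8)
  expect_identical(f$groups[[1]],
                   list(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L), c(1L, 2L)))

  # star: 6 distinct 2-node chains, eta = 3 keeps the lexicographically first
  star_snap <- make_snapshot(7, 1, c(0, 1:6), c(NA, rep(1, 6)))
  f2 <- build_snapshot_feature(star_snap, toy_areas(7, list(1:7)),
                               l_max = 4, eta = 3)
  expect_identical(f2$groups[[1]], list(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
})

test_that("groups are ordered by mean informed time, uninformed areas last", {
  snap <- make_snapshot(6, 1, 0:5, c(NA, 1:5))
  f <- build_snapshot_feature(snap, toy_areas(6, list(c(5, 6), c(1, 2))),
                              l_max = 4, eta = 8)
  expect_identical(f$area_order, c(2L, 1L))
  expect_identical(f$groups[[1]], list(c(1L, 2L)))
  expect_identical(f$groups[[2]], list(c(5L, 6L)))

  # area 2 (mean 0) precedes area 3 (mean 1.5); area 1 has no informed
  # observer and is pushed last
  snap2 <- make_snapshot(6, 4, c(NA, NA, NA, 0, 1, 2), c(NA, NA, NA, NA, 4, 5))
  f2 <- build_snapshot_feature(snap2, toy_areas(6, list(c(1, 2), c(3, 4), c(5, 6))),
                               l_max = 4, eta = 8)
  expect_identical(f2$area_order, c(2L, 3L, 1L))
})

test_that("a source-only snapshot yields all-empty groups", {
  snap <- make_snapshot(5, 2, c(NA, 0, NA, NA, NA), rep(NA_integer_, 5))
  f <- build_snapshot_feature(snap, toy_areas(5, list(1:3, 3:5)),
                              l_max = 4, eta = 8)
  expect_identical(lengths(f$groups), c(0L, 0L))
})

test_that("every emitted sequence is an in-area directed sub-path of the infection tree", {
  g <- generate_ba_graph(60, 2, 1.3, seed = 21)
  areas <- build_observation_areas(g, select_vital_nodes(g, 0.05), h = 1)
  for (seed in 1:6) {
    set.seed(seed)
    snap <- simulate_diffusion(g, sample.int(60, 1), 0.7)
    f <- build_snapshot_feature(snap, areas, l_max = 4, eta = 8)
    for (gi in seq_along(f$groups)) {
      area <- areas$areas[[f$area_order[gi]]]
      for (s in f$groups[[gi]]) {
        expect_true(all(s %in% area))
        expect_true(all(s %in% which(!is.na(snap$time))))
        expect_true(all(diff(snap$time[s]) > 0))
        if (length(s) > 1)
          expect_identical(snap$infector[s[-1]], s[-length(s)])
      }
    }
  }
})

test_that("feature construction agrees with an independent R oracle", {
  g <- generate_ws_graph(50, 2, 0.15, seed = 22)
  areas <- build_observation_areas(g, select_vital_nodes(g, 0.06), h = 1)
  for (seed in 1:5) {
    set.seed(seed)
    snap <- simulate_diffusion(g, sample.int(50, 1), 0.8)
    f <- build_snapshot_feature(snap, areas, l_max = 4, eta = 6)
    oracle <- r_feature_oracle(snap, areas, l_max = 4, eta = 6)
    expect_identical(f$area_order, as.integer(oracle$area_order))
    for (gi in seq_along(f$groups))
      expect_identical(f$groups[[gi]], lapply(oracle$groups[[gi]], as.integer))
  }
})

test_that("feature serialization writes one group per area", {
  snap <- make_snapshot(6, 1, 0:5, c(NA, 1:5))
  areas <- toy_areas(6, list(c(1, 2), c(5, 6)))
  f <- build_snapshot_feature(snap, areas, l_max = 4, eta = 8)
  p <- withr::local_tempfile(fileext = ".txt")
  write_snapshot_feature(f, p, areas)
  lines <- readLines(p)
  expect_length(grep("^# area", lines), 2)
})
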