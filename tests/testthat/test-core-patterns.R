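test_that("transect construction and file reading validate their input", {
  t <- transect(c(0, 1, 3), length = 4)
  expect_s3_class(t, "transect")
  expect_error(transect(c(0, 0, 1), 4), "strictly increasing")
  expect_error(transect(c(0, 5), 4), "outside")
  expect_error(transect(c(0, 1), 4, widths = c(1, -1)), "positive")

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,pos", "a,0", "b,1", "c,3"), tmp)
  t2 <- read_pattern(tmp, "transect", length = 4)
  expect_equal(t2$positions, c(0, 1, 3))

  writeLines(c("id,pos,width", "a,3,2", "b,0,2", "c,1,2"), tmp)
  t3 <- read_pattern(tmp, "transect", length = 4)
  expect_equal(t3$positions, c(0, 1, 3))       # sorted by position
  expect_length(t3$widths, 3)

  writeLines(c("id,pos", "a,0", "b,xx"), tmp)
  expect_error(read_pattern(tmp, "transect", length = 4), "non-numeric.*b")

  writeLines(c("id,x,y", "p1,0,0", "p2,1,1", "p3,1,1"), tmp)
  expect_error(read_pattern(tmp, "pattern2d"), "duplicate.*p3")
  writeLines(c("id,x", "p1,0"), tmp)
  expect_error(read_pattern(tmp, "pattern2d"), "missing column")
})

test_that("1-D nearest-neighbour distances honour topology", {
  expect_equal(nn_distances_1d(transect(c(0, 1, 2, 3), 4, "ring")),
               c(1, 1, 1, 1))
  expect_equal(nn_distances_1d(transect(c(0, 1, 3), 4, "line")), c(1, 1, 2))
  expect_equal(nn_distances_1d(transect(c(0.5, 9.5), 10, "ring")), c(1, 1))
  expect_error(nn_distances_1d(transect(2, 4)), "at least 2")
})

test_that("ring NN distances are invariant under rotation", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      pos <- sort(runif(15, 0, 100))
      t0 <- transect(pos, 100, "ring")
      delta <- runif(1, 0, 100)
      t1 <- transect(sort((pos + delta) %% 100), 100, "ring")
      expect_equal(sort(nn_distances_1d(t1)), sort(nn_distances_1d(t0)),
                   tolerance = 1e-10)
    }
  })
})

test_that("edge-to-edge gaps subtract the half-widths", {
  expect_equal(edge_gap_distances(transect(c(0, 100), 100,
                                           widths = c(20, 20))), 80)
  u <- transect((1:8 - 0.5) * 50, 400, "ring", widths = rep(10, 8))
  expect_equal(edge_gap_distances(u), rep(40, 8))
  expect_error(edge_gap_distances(transect(c(0, 10), 20,
                                           widths = c(15, 15))),
               "overlapping")
  expect_error(edge_gap_distances(transect(c(0, 10), 20)), "no widths")
})

test_that("Delaunay adjacency matches its definition on known geometries", {
  tri <- point_pattern(c(0, 1, 0.3), c(0, 0, 1), area = 1)
  adj <- delaunay_adjacency(tri)
  expect_equal(lengths(adj), c(2L, 2L, 2L))

  # hexagon ring + centre: the centre has all six ring points as neighbours
  hexc <- point_pattern(c(0, cos(0:5 * pi / 3)), c(0, sin(0:5 * pi / 3)),
                        area = 3)
  a <- delaunay_adjacency(hexc)
  expect_equal(length(a[[1]]), 6L)
  expect_setequal(a[[1]], 2:7)

  # four co-circular corners: degeneracy resolved deterministically
  sq <- point_pattern(c(0, 1, 1, 0), c(0, 0, 1, 1), area = 1)
  asq <- delaunay_adjacency(sq)
  expect_true(attr(asq, "jittered"))
  expect_equal(sum(lengths(asq)), 10L)  # 4 sides + exactly one diagonal
  expect_identical(delaunay_adjacency(sq)[[1]], asq[[1]])  # reproducible

  col <- point_pattern(0:4, rep(2, 5), area = 1)
  expect_error(delaunay_adjacency(col), "1-D")
})

test_that("adjacency is symmetric with no self-loops on random patterns", {
  for (seed in 1:8) {
    p <- gen_pattern2d("poisson", 30, seed = seed, area = 1e4)
    adj <- delaunay_adjacency(p)
    for (i in seq_along(adj)) {
      expect_false(i %in% adj[[i]])
      for (j in adj[[i]]) expect_true(i %in% adj[[j]])
    }
    expect_true(all(lengths(adj) >= 1))
  }
})

test_that("Delaunay NN distances equal the all-pairs oracle", {
  # unit square (either diagonal): every corner's NN distance is the side
  sq <- point_pattern(c(0, 1, 1, 0), c(0, 0, 1, 1), area = 1)
  expect_equal(nn_distances_2d(sq, delaunay_adjacency(sq)), rep(1, 4))

  hx <- gen_pattern2d("hexagonal", 64, seed = 1, s = 7)
  expect_equal(nn_distances_2d(hx, delaunay_adjacency(hx)), rep(7, 64),
               tolerance = 1e-9)

  for (seed in 1:10) {
    n <- sample(10:50, 1)
    p <- gen_pattern2d("poisson", n, seed = seed, area = 1e4)
    expect_equal(nn_distances_2d(p, delaunay_adjacency(p)), brute_nn(p),
                 tolerance = 1e-12)
  }
})

test_that("Delaunay edges agree with an independent circumcircle scan", {
  for (seed in 1:5) {
    p <- gen_pattern2d("poisson", 12, seed = seed + 100, area = 100)
    adj <- delaunay_adjacency(p)
    got <- adjacency_edges(adj)
    want <- brute_delaunay_edges(p$x, p$y)
    expect_equal(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
                 unname(want[order(want[, 1], want[, 2]), , drop = FALSE]))
  }
})

test_that("degree filtering keeps the well-embedded points", {
  hexc <- point_pattern(c(0, cos(0:5 * pi / 3)), c(0, sin(0:5 * pi / 3)),
                        area = 3)
  adj <- delaunay_adjacency(hexc)
  suppressMessages({
    centre_only <- filter_by_degree(hexc, adj, 5)
    expect_equal(attr(centre_only, "retained"), 1L)
    expect_equal(c(centre_only$x, centre_only$y), c(0, 0))

    all_kept <- filter_by_degree(hexc, adj, 0)
    expect_equal(attr(all_kept, "retained"), 7L)

    expect_warning(none <- filter_by_degree(hexc, adj, 99), "empty")
    expect_equal(attr(none, "retained"), 0L)
  })
})
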