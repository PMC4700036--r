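test_that("every generator is a pure function of its arguments", {
  t1 <- gen_transect("poisson", 50, 1000, seed = 31)
  t2 <- gen_transect("poisson", 50, 1000, seed = 31)
  expect_identical(t1, t2)
  expect_false(identical(t1, gen_transect("poisson", 50, 1000, seed = 32)))

  p1 <- gen_pattern2d("hardcore", 40, seed = 5, area = 1e4)
  p2 <- gen_pattern2d("hardcore", 40, seed = 5, area = 1e4)
  expect_identical(p1, p2)

  r1 <- gen_cell_rows(10, 5, seed = 2)
  r2 <- gen_cell_rows(10, 5, seed = 2)
  expect_identical(r1, r2)

  g1 <- gen_growth_insertion(growth_params(), n_events = 50, seed = 4)
  g2 <- gen_growth_insertion(growth_params(), n_events = 50, seed = 4)
  expect_identical(g1, g2)

  expect_error(gen_transect("uniform", 10, 100), "seed")
  expect_error(gen_pattern2d("poisson", 10, area = 1), "seed")
})

test_that("generated objects satisfy their class invariants by construction", {
  for (kind in c("uniform", "jittered", "poisson", "clustered")) {
    t <- gen_transect(kind, 30, 600, seed = 7)
    expect_s3_class(t, "transect")
    expect_false(is.unsorted(t$positions, strictly = TRUE))
    expect_true(all(t$positions >= 0 & t$positions <= t$length))
  }
  for (kind in c("poisson", "hexagonal", "hardcore", "gradient")) {
    p <- gen_pattern2d(kind, 25, seed = 7, area = 1e4, s = 10)
    expect_s3_class(p, "point_pattern")
    expect_false(anyDuplicated(cbind(p$x, p$y)) > 0)
  }
})

test_that("transect kinds produce their signature order indices", {
  u <- gen_transect("uniform", 37, 7225, seed = 1)
  expect_equal(r_index_from_transect(u)$r_value, 2, tolerance = 1e-9)
  cl <- gen_transect("clustered", 80, 8000, seed = 3)
  expect_lt(r_index_from_transect(cl)$r_value, 0.2)
})

test_that("hard-core generation errors once the region saturates", {
  expect_error(gen_pattern2d("hardcore", 200, seed = 1, area = 100,
                             r_min = 5, max_tries = 50),
               "saturation")
})

test_that("zero-slope gradients decorrelate spacing from depth", {
  cors <- vapply(1:10, function(i) {
    p <- gen_pattern2d("gradient", 120, seed = i, slope = 0, s0 = 10,
                       noise_sd = 1)
    gradient_correlation(nn_distances_2d(p, delaunay_adjacency(p)), p$labels)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("a weak positive slope is sign-recovered almost surely", {
  # slope set to half the relative jitter scale
  hits <- vapply(1:200, function(i) {
    p <- gen_pattern2d("gradient", 100, seed = 1000 + i, slope = 0.005,
                       s0 = 10, noise_sd = 1)
    gradient_correlation(nn_distances_2d(p, delaunay_adjacency(p)),
                         p$labels) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("growth-insertion output is a consistent measured transect", {
  gp <- growth_params(m = 11.41)
  g <- gen_growth_insertion(gp, asymmetry = 114.3 / 200.2, vein_width = 28,
                            n_events = 500, seed = 11)
  gaps <- edge_gap_distances(g)
  expect_length(gaps, length(g$positions) - 1)
  # gaps stay below the (post-growth) doubling threshold and above the
  # smallest daughter a just-triggered parent can produce
  d_min <- gp$d0 * gp$m
  expect_lt(max(gaps), 2 * d_min * gp$a)
  expect_gte(min(gaps), (1 - 114.3 / 200.2) * (2 * d_min - 28) * 0.999)
  # daughter asymmetry: by construction of the insertion bookkeeping the
  # large:small ratio matches the measured 114.3:85.9
  ev <- insertion_event(228.2, asymmetry = 114.3 / 200.2, vein_width = 28)
  expect_equal(ev$d_large / ev$d_small, 114.3 / 85.9, tolerance = 1e-12)
})

test_that("cell-row batches share the Monte Carlo code path", {
  rows <- gen_cell_rows(8, 200, seed = 44)
  counts <- vapply(rows, function(r) {
    tl <- tally(r); c(tl$one_celled, tl$one_celled + tl$two_celled)
  }, numeric(2))
  pooled <- sum(counts[1, ]) / sum(counts[2, ])
  mc <- monte_carlo_frequency(8, 200, seed = 44)
  expect_identical(mc$frequency, pooled)
  expect_true(all(vapply(gen_cell_rows(1, 5, seed = 1), function(r) {
    identical(unclass(r), c("P", "S", "P", "S", "P"))
  }, logical(1))))
})
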