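test_that("the conversion rule forces the known small-row outcomes", {
  # one free cell: the only completion is P S P S P
  for (seed in 1:5) {
    expect_identical(unclass(simulate_row(1, seed = seed)),
                     c("P", "S", "P", "S", "P"))
  }
  # three free cells: exactly two completions exist
  rows <- vapply(1:30, function(s) paste(simulate_row(3, seed = s),
                                         collapse = ""), character(1))
  expect_true(all(rows %in% c("PSPSPSP", "PSSPSSP")))
  expect_setequal(unique(rows), c("PSPSPSP", "PSSPSSP"))
})

test_that("completed rows never hold adjacent P or S-runs beyond two", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      n <- sample(1:50, 1)
      row <- unclass(simulate_row(n))
      expect_false(any(row == "F"))
      ppos <- which(row == "P")
      runs <- diff(ppos) - 1L
      expect_true(all(runs %in% c(1L, 2L)))
    }
  })
})

test_that("tallies count S-runs between P cells, flanks included", {
  expect_equal(unclass(tally(cell_row(c("P","S","P","S","P"))))[1:2],
               list(one_celled = 2L, two_celled = 0L))
  t3 <- tally(cell_row(strsplit("PSPSPSP", "")[[1]]))
  expect_equal(t3$one_celled, 3L)
  t2 <- tally(cell_row(strsplit("PSSPSSP", "")[[1]]))
  expect_equal(t2$two_celled, 2L)
  expect_equal(t2$frequency, 0)
  expect_error(tally(cell_row(c("P", "S", "F", "S", "P"))), "free cells")
})

test_that("equal-weight order enumeration matches the closed-form oracle", {
  # pooled counts must equal sum over maximal independent sets of k! times
  # that configuration's run tallies (two independent routes)
  for (n in 1:8) {
    got <- enumerate_permutations(n)
    want <- mis_enumeration_oracle(n)
    expect_identical(c(got$favorable, got$total), unname(want),
                     info = paste("n =", n))
  }
  # small-row values verified by hand enumeration
  expect_equal(sapply(1:5, function(n) {
    e <- enumerate_permutations(n); c(e$favorable, e$total)
  }), matrix(c(2, 2, 2, 4, 6, 8, 12, 18, 30, 42), nrow = 2))
  expect_error(enumerate_permutations(13), "guard")
})

test_that("configuration-weight enumeration gives the combination values", {
  e1 <- enumerate_combinations(1)
  expect_equal(c(e1$favorable, e1$total), c(2, 2))
  e2 <- enumerate_combinations(2)   # hand enumeration: PSPSSP, PSSPSP
  expect_equal(c(e2$favorable, e2$total, e2$n_cases), c(2, 4, 2))
  e3 <- enumerate_combinations(3)
  expect_equal(c(e3$favorable, e3$total), c(3, 5))
  expect_equal(e3$frequency, 0.6)
})

test_that("the spacing frequency oscillates with local maxima at odd rows", {
  freq <- vapply(1:6, function(n) enumerate_permutations(n)$frequency,
                 numeric(1))
  expect_gt(freq[1], freq[2])   # 1.000 > 0.500
  expect_gt(freq[3], freq[2])   # 0.750 peak at n = 3
  expect_gt(freq[3], freq[4])
  expect_gt(freq[5], freq[4])   # peak at n = 5
  expect_gt(freq[5], freq[6])
})

test_that("Monte Carlo pools counts and agrees with the exact dynamics", {
  # two free cells: every completion gives one of each separation
  mc2 <- monte_carlo_frequency(2, 500, seed = 8)
  expect_identical(mc2$frequency, 0.5)

  # three free cells: pooled expectation 0.75 (the 2/3 vs 1/3 outcome split)
  mc3 <- monte_carlo_frequency(3, 30000, seed = 12)
  se3 <- pooled_freq_se(attr(mc3, "per_row"))
  expect_lt(abs(mc3$frequency - 0.75), 3 * se3)

  # pooling, not per-row averaging: per-row mean for n = 3 would be 2/3
  expect_gt(mc3$frequency, 0.72)

  dyn3 <- dynamics_exact_frequency(3)
  expect_equal(dyn3$frequency, 0.75, tolerance = 1e-12)
  dyn5 <- dynamics_exact_frequency(5)
  expect_equal(dyn5$frequency, 9 / 13, tolerance = 1e-12)
})

test_that("the dynamics-exact values differ from equal-weight enumeration", {
  # the two weightings agree for rows up to four free cells, then part ways
  for (n in 1:4) {
    expect_equal(dynamics_exact_frequency(n)$frequency,
                 enumerate_permutations(n)$frequency, tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(dynamics_exact_frequency(5)$frequency,
                                enumerate_permutations(5)$frequency)))
})

test_that("cell counts convert to centre-to-centre distances", {
  expect_equal(spacing_to_distance(1), 2)
  expect_equal(spacing_to_distance(2), 3)
  expect_error(spacing_to_distance(3), "1- or 2-celled")
})

test_that("the children's-slide pdf is the stated binomial", {
  s1 <- slide_pdf(1, p_small = 0.69, m = 1)
  expect_equal(s1$mass, c(0.69, 0.31))
  expect_equal(s1$support, c(2, 3))

  s5 <- slide_pdf(5, p_small = 0.69, m = 70)
  expect_length(s5$mass, 6)                     # the peripheral-bundle fit
  expect_equal(s5$support, (2:7) * 70)
  expect_equal(sum(s5$mass), 1, tolerance = 1e-12)
  expect_equal(s5$mass, dbinom(0:5, 5, 0.31), tolerance = 1e-12)
  # slide signature: frequency at the longest distance is near zero
  expect_lt(s5$mass[6] / max(s5$mass), 0.01)

  expect_error(slide_pdf(0), "positive integer")
  expect_error(slide_pdf(2, p_small = 1.2), "in \\(0, 1\\)")
})
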