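test_that("phi percentiles interpolate the percent-coarser curve", {
  # single class bounded (1, 0.5) mm: phi runs 0 to 1, median midway
  g <- grain_size_distribution(c(1, 0.5), 100)
  expect_equal(percentile_phi(g, 50), 0.5)
  expect_equal(percentile_phi(g, 25), 0.25)

  # symmetric two-class 50/50: median at the shared bound
  g2 <- grain_size_distribution(c(2, 1, 0.5), c(50, 50))
  expect_equal(percentile_phi(g2, 50), 0)   # phi of 1 mm

  expect_error(percentile_phi(g, 0), "strictly inside")
  expect_error(percentile_phi(g, 100), "strictly inside")
})

test_that("three-class curve matches the spreadsheet-style hand oracle", {
  # bounds (4,2,1,0.5) mm -> phi (-2,-1,0,1); percents (20,30,50);
  # cumulative coarser at bounds: 0, 20, 50, 100 (hand-interpolated)
  g <- grain_size_distribution(c(4, 2, 1, 0.5), c(20, 30, 50))
  expect_equal(percentile_phi(g, 16), -1.2)
  expect_equal(percentile_phi(g, 84), 0.68)
  expect_equal(percentile_phi(g, 5), -1.75)
  expect_equal(percentile_phi(g, 95), 0.9)
  fw <- folk_ward(g)
  expect_equal(fw$mean_phi, (-1.2 + 0 + 0.68) / 3)
  expect_equal(fw$sorting_phi, (0.68 - (-1.2)) / 4 + (0.9 - (-1.75)) / 6.6)
  expect_equal(fw$sorting_geometric, 2^fw$sorting_phi)
  expect_equal(fw$skewness,
               (-1.2 + 0.68) / (2 * 1.88) + (-1.75 + 0.9) / (2 * 2.65))
  expect_equal(fw$kurtosis, 2.65 / (2.44 * (0.5 - (-5 / 6))))
  expect_equal(fw$d50_mm, 1)
  expect_equal(percent_sand(g), 80)
})

test_that("sorting approaches 1 in the zero-spread limit", {
  g <- grain_size_distribution(c(1.0005, 0.9995), 100)
  fw <- folk_ward(g)
  expect_lt(fw$sorting_geometric, 1.002)
  expect_gte(fw$sorting_geometric, 1)
})

test_that("percent sand uses the 0.0625-2 mm window with phi pro-rata", {
  expect_equal(percent_sand(grain_size_distribution(c(0.5, 0.25), 100)), 100)
  expect_equal(percent_sand(grain_size_distribution(c(8, 4), 100)), 0)
  # class 1-4 mm straddles the 2 mm boundary: half its phi width is sand
  g <- grain_size_distribution(c(8, 4, 1), c(50, 50))
  expect_equal(percent_sand(g), 25)
})

test_that("percentiles are monotone and sorting >= 1 on random ladders", {
  set.seed(21)
  for (rep in 1:25) {
    nb <- sample(4:12, 1)
    bounds <- sort(2^runif(nb, -4, 8), decreasing = TRUE)
    pct <- runif(nb - 1)
    pct <- pct / sum(pct) * 100
    g <- grain_size_distribution(bounds, pct)
    q <- vapply(c(5, 16, 50, 84, 95), function(p) percentile_phi(g, p), 0)
    expect_true(all(diff(q) >= -1e-12))
    fw <- folk_ward(g)
    expect_gte(fw$sorting_geometric, 1)
    # d50 within the data range
    expect_lte(fw$d50_mm, max(bounds) + 1e-12)
    expect_gte(fw$d50_mm, min(bounds) - 1e-12)
  }
})

test_that("statistics are invariant to rescaling of class percents", {
  g1 <- grain_size_distribution(c(4, 2, 1, 0.5), c(20, 30, 50))
  # same shape with a within-tolerance total is renormalized internally
  g2 <- grain_size_distribution(c(4, 2, 1, 0.5), c(20, 30, 50) * 1.004)
  expect_error(grain_size_distribution(c(4, 2, 1, 0.5),
                                       c(20, 30, 50) * 1.2), "sum to 100")
  expect_equal(folk_ward(g1)$sorting_phi, folk_ward(g2)$sorting_phi)
  expect_equal(percent_sand(g1), percent_sand(g2))
})

test_that("open-ended extreme classes are closed one phi unit out", {
  # 3 bounds, 4 percents: first/last classes are open-ended
  g <- grain_size_distribution(c(4, 2, 1), c(10, 40, 40, 10))
  expect_equal(g$bounds_mm, c(8, 4, 2, 1, 0.5))
  expect_equal(sum(g$percent), 100)
})

test_that("the distribution constructor enforces its invariants", {
  expect_error(grain_size_distribution(c(1, 2), c(100)), "decreasing")
  expect_error(grain_size_distribution(c(2, 1, 0.5), c(-5, 105)),
               "non-negative")
  expect_error(grain_size_distribution(c(2, 1, 0.5), c(30, 30)),
               "sum to 100")
})
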