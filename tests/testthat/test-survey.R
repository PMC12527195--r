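test_that("wrack aggregation is the arithmetic mean over quadrats", {
  q <- data.frame(site_id = "s", percent_cover_total = c(40, 20),
                  percent_algae = c(20, 15), percent_eelgrass = c(5, 5),
                  percent_terrestrial = c(10, 0),
                  wrack_width_m = c(4, 2), wrack_depth_cm = c(2, 1))
  expect_equal(unname(aggregate_wrack(q)), c(30, 5, 1.5, 3))

  zero <- data.frame(site_id = "s", percent_cover_total = 0,
                     percent_algae = 0, percent_eelgrass = 0,
                     percent_terrestrial = 0, wrack_width_m = 0,
                     wrack_depth_cm = 0)[rep(1, 10), ]
  expect_equal(unname(aggregate_wrack(zero)), c(0, 0, 0, 0))
  expect_error(aggregate_wrack(zero[0, ]), "no quadrats")
})

test_that("aggregation means are invariant to record order", {
  set.seed(5)
  q <- data.frame(site_id = "s", percent_cover_total = runif(12, 20, 80),
                  percent_algae = 0, percent_eelgrass = 0,
                  percent_terrestrial = runif(12, 0, 10),
                  wrack_width_m = runif(12, 0, 6),
                  wrack_depth_cm = runif(12, 0, 4))
  expect_equal(aggregate_wrack(q), aggregate_wrack(q[sample(12), ]))
})

test_that("fish density scales counts by surveyed area to per 100 m2", {
  expect_equal(fish_density(0, 75, 2), 0)
  expect_equal(fish_density(10, 50, 2), 10)
  expect_equal(fish_density(13, 50, 1), 26)
  # linear in count, inverse in length x visibility
  expect_equal(fish_density(20, 50, 2), 2 * fish_density(10, 50, 2))
  expect_equal(fish_density(10, 100, 2), fish_density(10, 50, 2) / 2)
  expect_error(fish_density(1, 0, 2), "transect_length")
  expect_error(fish_density(1, 50, -1), "visibility")
})

test_that("fallout density and richness follow the trap-area scaling", {
  empty <- fallout_density(c(a = 0, b = 0), 0.10)
  expect_equal(empty$density, 0)
  expect_equal(empty$richness, 0)
  expect_equal(fallout_density(c(a = 10), 0.10)$density, 100)
  expect_equal(fallout_density(c(a = 5, b = 4, c = 1), 0.10)$richness, 3)
  expect_error(fallout_density(c(a = 1), 0), "trap_area")
})

test_that("overhang percent merges overlapping intervals and is capped", {
  expect_equal(overhang_percent(matrix(numeric(0), 0, 2), 50), 0)
  expect_equal(overhang_percent(rbind(c(0, 10), c(5, 20)), 50), 40)
  expect_equal(overhang_percent(rbind(c(0, 50)), 50), 100)
  # heavy overlap never exceeds 100
  iv <- rbind(c(0, 30), c(0, 40), c(10, 50), c(5, 45))
  expect_lte(overhang_percent(iv, 50), 100)
  expect_error(overhang_percent(rbind(c(-1, 10)), 50), "outside")
  expect_error(overhang_percent(rbind(c(0, 51)), 50), "outside")
})

test_that("feeding contingency reproduces the printed study counts", {
  fx <- feeding_fixture()
  tab <- feeding_contingency(fx$snorkel, fx$registry)
  expect_equal(unname(tab),
               rbind(c(1L, 0L, 4L, 6L), c(15L, 7L, 6L, 6L)))
  expect_equal(colnames(tab), bb_treatments())

  none <- fx$snorkel
  none$feeding_observed <- 0L
  expect_equal(unname(feeding_contingency(none, fx$registry)[1, ]),
               rep(0L, 4))

  drop_pl <- fx$snorkel[fx$snorkel$site_id != "s2", ]
  expect_error(feeding_contingency(drop_pl, fx$registry), "ProtectLow")
})

test_that("site metric table enforces schema, missingness and determinism", {
  cfg <- simulation_config(seed = 10)
  rec <- simulate_sites(cfg)
  tab <- site_metric_table(rec)
  expect_s3_class(tab, "site_metric_table")
  expect_equal(dim(tab), c(20, 33))
  expect_equal(names(tab)[-(1:3)], bb_metric_names())

  # rebuilding from the same records is identical
  expect_identical(tab, site_metric_table(rec))

  # a site with no fallout data gets NA, not zero
  rec2 <- rec
  rec2$fallout <- rec2$fallout[rec2$fallout$site_id !=
                                 rec2$registry$site_id[1], ]
  tab2 <- site_metric_table(rec2)
  expect_true(is.na(tab2[1, "Fallout Trap Density (m-2)"]))
  expect_true(is.na(tab2[1, "Fallout Trap Taxa Richness"]))

  dup <- data.frame(site_id = c("a", "a"), stringsAsFactors = FALSE)
  dup[["% Wrack Cover"]] <- c(1, 2)
  expect_error(build_site_metric_table(rec$registry, dup), "duplicate")

  bad <- data.frame(site_id = "a", stringsAsFactors = FALSE)
  bad[["Not A Metric"]] <- 1
  expect_error(build_site_metric_table(rec$registry, bad), "unknown metric")
})

test_that("a pre-averaged treatment table passes the scale-bar schema", {
  ref <- reference_treatment_means()
  expect_equal(nrow(ref), 30)
  sb <- scale_bar(ref)
  expect_s3_class(sb, "scale_bar")
})
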