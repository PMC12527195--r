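test_that("the same seed reproduces byte-identical survey directories", {
  cfg <- simulation_config(seed = 9)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_survey_dir(simulate_sites(cfg), d1)
  write_survey_dir(simulate_sites(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("different seeds give different replicate draws", {
  a <- simulate_sites(simulation_config(seed = 1))
  b <- simulate_sites(simulation_config(seed = 2))
  expect_false(identical(a$wrack, b$wrack))
})

test_that("emitted records pass every schema validator", {
  rec <- simulate_sites(simulation_config(seed = 13))
  expect_silent(validate_registry(rec$registry))
  expect_silent(validate_wrack(rec$wrack))
  expect_silent(validate_loglines(rec$loglines))
  expect_silent(validate_snorkel(rec$snorkel))
  expect_silent(validate_fallout(rec$fallout))
  expect_silent(validate_mllw(rec$mllw))
  v <- rec$vegetation
  expect_silent(validate_vegetation(v$transects, v$overhangs, v$patches,
                                    v$species))
})

test_that("Restore Low fallout assemblages are mostly non-flying taxa", {
  rec <- simulate_sites(simulation_config(seed = 17))
  fo <- rec$fallout
  rl_sites <- rec$registry$site_id[rec$registry$treatment == "RestoreLow"]
  sub <- fo[fo$site_id %in% rl_sites, ]
  taxa <- setdiff(names(fo), c("site_id", "trap_id", "trap_area_m2",
                               "deploy_hours"))
  nonflying <- intersect(c("acari", "collembola", "araneae"), taxa)
  frac <- sum(sub[, nonflying]) / sum(sub[, taxa])
  expect_gte(frac, 0.80)
})

test_that("simulated profiles round-trip the configured geomorphology", {
  d <- tidal_datums(3.3, 2.0, 0.0)
  # encroachment +0.27 (the armored-high treatment mean) comes back exactly
  p <- bluffbeach:::.profile_for(0.27, 0.11, 39.5, d)
  gm <- geomorph_metrics(p, d)
  expect_equal(gm$relative_encroachment, 0.27)
  expect_equal(gm$slope_toe_msl, 0.11, tolerance = 1e-9)
  expect_equal(gm$width_toe_mllw, 39.5, tolerance = 1e-9)
  # width 49.7 target round-trips too
  p2 <- bluffbeach:::.profile_for(-0.12, 0.12, 49.7, d)
  expect_equal(width_toe_mllw(p2, d), 49.7, tolerance = 1e-9)
  # infeasible geometry is refused
  expect_error(bluffbeach:::.profile_for(3.5, 0.1, 40, d), "infeasible")
  sp <- simulate_profiles(simulation_config(seed = 19, region_sd = 0))
  gm_all <- vapply(sp$profiles, function(p)
    geomorph_metrics(p, sp$datums)$relative_encroachment, 0)
  ref <- reference_treatment_means()
  enc <- unlist(ref[ref$metric == "Relative Encroachment (m)",
                    bb_treatments()])
  reg <- bluffbeach:::.default_registry(simulation_config(seed = 19))
  expect_equal(unname(gm_all), unname(enc[reg$treatment]),
               tolerance = 1e-9)
})

test_that("grain-size simulation hits sorting and sand targets", {
  g <- simulate_grainsize_one(6.5, 42)
  fw <- folk_ward(g)
  expect_lt(abs(fw$sorting_geometric / 6.5 - 1), 0.10)
  expect_lt(abs(percent_sand(g) - 42), 5)

  g2 <- simulate_grainsize_one(3.3, 60)
  expect_lt(abs(percent_sand(g2) - 60), 5)
  expect_lt(abs(folk_ward(g2)$sorting_geometric / 3.3 - 1), 0.10)

  # near-zero spread: sorting approaches the ladder's well-sorted floor
  g3 <- simulate_grainsize_one(1.0, 60)
  expect_lt(folk_ward(g3)$sorting_geometric, 1.4)
})

test_that("the config rejects invalid composition profiles", {
  bad <- .default_fallout_taxa <- list(
    ProtectHigh = c(a = 0.5, b = 0.4),   # sums to 0.9
    ProtectLow = c(a = 1), RestoreHigh = c(a = 1), RestoreLow = c(a = 1))
  expect_error(simulation_config(fallout_composition = bad), "sum to 1")
})
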