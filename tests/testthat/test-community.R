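test_that("abundance transforms are the stated elementwise maps", {
  m <- rbind(a = c(0, 3, 4), b = c(1, 0, 9))
  expect_equal(transform_abundance(m, "log1"), log(m + 1))
  expect_equal(transform_abundance(m, "sqrt"), sqrt(m))
  expect_equal(transform_abundance(m, "none"), m)
  z <- matrix(0, 2, 3)
  expect_equal(transform_abundance(z, "log1"), z)
  expect_equal(transform_abundance(z, "sqrt"), z)
  expect_error(transform_abundance(-m), "non-negative")
})

test_that("rare-taxa filter keeps taxa reaching 3% in any one sample", {
  # taxon at 2% everywhere is dropped; 50% in one sample is kept
  m <- rbind(s1 = c(2, 50, 48), s2 = c(2, 0, 98), s3 = c(2, 0, 98))
  colnames(m) <- c("rare", "patchy", "common")
  kept <- rare_taxa_filter(m, 0.03)
  expect_equal(colnames(kept), c("patchy", "common"))

  # exhaustive brute-force oracle on a random toy matrix
  set.seed(41)
  toy <- matrix(rpois(12, 4), 3, 4,
                dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
  toy[1, ] <- toy[1, ] + 1   # ensure positive row totals
  keep <- logical(4)
  for (j in 1:4) for (i in 1:3)
    if (toy[i, j] / sum(toy[i, ]) >= 0.03) keep[j] <- TRUE
  expect_equal(colnames(rare_taxa_filter(toy)), colnames(toy)[keep])

  # idempotence
  expect_equal(rare_taxa_filter(rare_taxa_filter(toy)),
               rare_taxa_filter(toy))
  expect_error(rare_taxa_filter(matrix(c(50, 50), 1, 2), threshold = 0.7),
               "all taxa dropped")
})

test_that("Bray-Curtis matches hand arithmetic and the metric axioms", {
  m <- rbind(a = c(1, 2, 0), b = c(0, 2, 2))
  expect_equal(bray_curtis(m)["a", "b"], 3 / 7)
  same <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(bray_curtis(same)["a", "b"], 0)
  disj <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  zz <- rbind(a = c(0, 0), b = c(0, 0))
  expect_equal(bray_curtis(zz)["a", "b"], 0)   # 0/0 convention

  set.seed(51)
  x <- matrix(rpois(60, 3), 6, 10)
  d <- bray_curtis(x)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 6))
  expect_true(all(d >= 0 & d <= 1))
  # invariant to taxon column order
  expect_equal(bray_curtis(x[, sample(10)]), d)
})

test_that("Bray-Curtis agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(52)
  x <- matrix(rpois(50, 5) + 1, 5, 10)
  expect_equal(as.vector(stats::as.dist(bray_curtis(x))),
               as.vector(vegan::vegdist(x, "bray")), tolerance = 1e-12)
})

test_that("PERMANOVA partitions sums of squares and matches vegan's F", {
  set.seed(61)
  x <- rbind(matrix(rpois(40, 3), 4, 10), matrix(rpois(40, 8), 4, 10))
  g <- rep(c("A", "B"), each = 4)
  d <- bray_curtis(x)
  pv <- permanova(d, g, n_perm = 99, seed = 1)
  expect_equal(pv$ss_between + pv$ss_within, pv$ss_total, tolerance = 1e-12)
  expect_equal(pv$df_between, 1)
  expect_equal(pv$df_within, 6)
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 99)
  expect_equal(pv$pseudo_F, ad$F[1], tolerance = 1e-10)
})

test_that("exhaustive PERMANOVA equals brute-force enumeration", {
  set.seed(62)
  x <- matrix(rpois(36, 4), 6, 6)
  g <- rep(c("A", "B", "C"), each = 2)
  d <- bray_curtis(x)
  pv <- permanova(d, g, exhaustive = TRUE)
  # independent route: recursive enumerator + explicit-loop pseudo-F
  f_obs <- brute_pseudo_f(d, g)
  expect_equal(pv$pseudo_F, f_obs, tolerance = 1e-12)
  perms <- enumerate_perms(6L)
  f_all <- vapply(perms, function(idx) brute_pseudo_f(d, g[idx]), 0)
  expect_equal(pv$n_permutations, 720)
  expect_equal(pv$p_value, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
})

test_that("strongly separated groups give a small PERMANOVA p", {
  set.seed(63)
  x <- rbind(matrix(rpois(30, 2), 5, 6), matrix(rpois(30, 40), 5, 6))
  g <- rep(c("lo", "hi"), each = 5)
  pv <- permanova(bray_curtis(x), g, n_perm = 199, seed = 2)
  expect_lte(pv$p_value, 0.05)
  expect_gte(pv$p_value, 1 / 200)
})

test_that("restricted permutations stay within strata", {
  set.seed(64)
  strata <- rep(c("r1", "r2"), each = 4)
  x <- matrix(rpois(48, 5), 8, 6)
  g <- rep(c("A", "B"), 4)
  pv <- permanova(bray_curtis(x), g, n_perm = 99, strata = strata,
                  seed = 3)
  expect_s3_class(pv, "permanova")
  expect_error(permanova(bray_curtis(x), g, n_perm = 99,
                         strata = strata[1:3]), "strata inconsistent")
  expect_error(permanova(bray_curtis(x), c(g[-1], "C"), n_perm = 99),
               ">= 2 samples")
})

test_that("pairwise PERMANOVA mirrors the study's qualitative pattern", {
  # ProtectHigh and ProtectLow share composition; the two Restore
  # assemblages are distinct from everything
  set.seed(65)
  base <- c(60, 45, 30, 15, 6, 3)
  mk <- function(shift, n = 5) t(vapply(seq_len(n), function(i)
    rpois(6, pmax(base[shift], 0.5)), numeric(6)))
  ph <- mk(1:6)
  x <- rbind(ph, ph + matrix(rpois(30, 1), 5, 6),   # PL echoes PH
             mk(c(4, 5, 6, 1, 2, 3)), mk(c(6, 5, 4, 3, 2, 1)))
  g <- rep(bb_treatments(), each = 5)
  pp <- pairwise_permanova(bray_curtis(x), g, n_perm = 199, seed = 4)
  expect_equal(nrow(pp), 6)
  ph_pl <- pp$p_value[pp$group1 == "ProtectHigh" &
                        pp$group2 == "ProtectLow"]
  expect_gt(ph_pl, 0.05)
  others <- pp$p_value[!(pp$group1 == "ProtectHigh" &
                           pp$group2 == "ProtectLow")]
  expect_true(all(others < 0.05))
  # a pair's result equals a two-group run on only those samples
  sel <- g %in% c("ProtectHigh", "RestoreLow")
  solo <- permanova(bray_curtis(x[sel, ]), g[sel], n_perm = 199, seed = 4)
  row <- pp[pp$group1 == "ProtectHigh" & pp$group2 == "RestoreLow", ]
  expect_equal(row$pseudo_F, solo$pseudo_F, tolerance = 1e-12)
})

test_that("chi-squared independence matches hand and reference values", {
  # table equal to its expected values
  even <- rbind(c(10, 10), c(10, 10))
  res <- chi_square_independence(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  diag2 <- rbind(c(10, 0), c(0, 10))
  res2 <- chi_square_independence(diag2)
  expect_equal(res2$statistic, 20)
  expect_equal(res2$df, 1)

  # brute-force E-table comparison against stats::chisq.test on random tables
  set.seed(71)
  for (rep in 1:10) {
    tb <- matrix(rpois(8, 6) + 1, 2, 4)
    mine <- chi_square_independence(tb)
    ref <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(mine$expected, unname(ref$expected) + 0 * mine$expected,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))),
               "zero margin")
  expect_error(chi_square_independence(rbind(c(0.5, 1), c(1, 2))),
               "integers")
})

test_that("the stratified metric test behaves at the null and under effect", {
  # all values equal: every p is 1
  tr <- rep(bb_treatments(), each = 5)
  reg <- rep(bb_regions(), times = 4)
  same <- permutation_metric_test(rep(3, 20), tr, strata = reg,
                                  n_perm = 99, seed = 1)
  expect_true(all(same$p_value == 1))

  # a massive injected ProtectHigh-RestoreLow contrast is detected
  # (free permutations: with only five regions the restricted two-group
  # null has 32 relabelings, so its smallest two-sided p is 1/16)
  set.seed(72)
  v <- rnorm(20, 0, 1)
  v[tr == "ProtectHigh"] <- v[tr == "ProtectHigh"] + 12
  eff <- permutation_metric_test(v, tr, n_perm = 199, seed = 2)
  row <- eff[eff$group1 == "ProtectHigh" & eff$group2 == "RestoreLow", ]
  expect_lt(row$p_value, 0.05)
  # under restricted permutations the same contrast sits at the floor of
  # the achievable p grid
  eff_s <- permutation_metric_test(v, tr, strata = reg, n_perm = 199,
                                   seed = 2)
  row_s <- eff_s[eff_s$group1 == "ProtectHigh" &
                   eff_s$group2 == "RestoreLow", ]
  expect_lt(row_s$p_value, 0.12)

  expect_error(permutation_metric_test(v, tr, strata = reg[1:3]),
               "strata inconsistent")
  expect_error(permutation_metric_test(v[1:5], c("A", "A", "B", "B", "C"),
                                       n_perm = 99), ">= 2 sites")
})

test_that("the metric test is calibrated at the null and powered", {
  # type-I error at alpha = 0.05 over 1000 null simulations (two groups of
  # five exchangeable sites; free permutations give a near-continuous grid)
  set.seed(81)
  tr <- rep(c("A", "B"), each = 5)
  rej <- 0L
  for (sim in 1:1000) {
    v <- rnorm(10)
    p <- permutation_metric_test(v, tr, n_perm = 99)$p_value
    if (p <= 0.05) rej <- rej + 1L
  }
  rate <- rej / 1000
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)

  # power >= 0.9 for a 5-SD shift over 200 simulations
  hit <- 0L
  for (sim in 1:200) {
    v <- rnorm(10)
    v[tr == "A"] <- v[tr == "A"] + 5
    p <- permutation_metric_test(v, tr, n_perm = 99)$p_value
    if (p <= 0.05) hit <- hit + 1L
  }
  expect_gte(hit / 200, 0.9)
})
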