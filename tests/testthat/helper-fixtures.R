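# Shared fixture builders: everything is generated in code at test time.

# snorkel records reproducing the field study's printed feeding counts:
# ProtectHigh 1/16, ProtectLow 0/7, RestoreHigh 4/10, RestoreLow 6/12
feeding_fixture <- function() {
  counts <- data.frame(
    treatment = c("ProtectHigh", "ProtectLow", "RestoreHigh", "RestoreLow"),
    feeding = c(1L, 0L, 4L, 6L),
    events = c(16L, 7L, 10L, 12L),
    stringsAsFactors = FALSE)
  registry <- data.frame(
    site_id = paste0("s", 1:4),
    treatment = counts$treatment,
    region = rep("PennCove", 4),
    facing_degrees = 190, bluff_height_m = 10, bluff_exposure_m2 = 0,
    toe_index = 1L, stringsAsFactors = FALSE)
  snorkel <- data.frame(
    site_id = paste0("s", 1:4), season = "spring",
    transect_length_m = 50, visibility_m = 2,
    total_fish = 0L, juv_salmon = 0L, forage_fish = 0L, other_fish = 0L,
    feeding_observed = counts$feeding,
    salmon_observation_events = counts$events,
    stringsAsFactors = FALSE)
  list(registry = registry, snorkel = snorkel)
}

# linear beach profile dropping from a toe elevation at a constant slope
linear_profile <- function(toe_elev, slope, length_m = 60, n = 7) {
  x <- seq(0, length_m, length.out = n)
  elevation_profile(x, toe_elev - slope * x)
}

# independent brute-force pseudo-F from a distance matrix (explicit loops,
# written separately from the package implementation)
brute_pseudo_f <- function(d, groups) {
  n <- nrow(d)
  ss_t <- 0
  for (i in seq_len(n - 1)) for (k in (i + 1):n) ss_t <- ss_t + d[i, k]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in unique(groups)) {
    s <- which(groups == g)
    if (length(s) > 1) {
      acc <- 0
      for (i in seq_along(s)[-length(s)])
        for (k in (i + 1):length(s)) acc <- acc + d[s[i], s[k]]^2
      ss_w <- ss_w + acc / length(s)
    }
  }
  a <- length(unique(groups))
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# independent permutation enumerator (recursive, distinct from the package's)
enumerate_perms <- function(n) {
  if (n == 1) return(list(1L))
  res <- list()
  for (p in enumerate_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      res[[length(res) + 1L]] <- append(p, n, after = pos)
    }
  }
  res
}
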